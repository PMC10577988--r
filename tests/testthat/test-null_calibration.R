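test_that("permutation nulls are reproducible and labelled", {
  trajs <- lapply(1:4, function(i)
    simulate_group(sim_config(duration_s = 30, attraction = 0, seed = i)))
  n1 <- permute_null(trajs, "cross_group", n = 25, seed = 99)
  n2 <- permute_null(trajs, "cross_group", n = 25, seed = 99)
  expect_identical(n1$replicate_scores, n2$replicate_scores)
  expect_true(all(n1$replicate_scores >= 0))
  expect_equal(n1$method, "cross_group")
  n3 <- permute_null(trajs, "cross_group", n = 25, seed = 100)
  expect_false(identical(n1$replicate_scores, n3$replicate_scores))
})

test_that("cross_group refuses too few groups", {
  trajs <- lapply(1:2, function(i)
    simulate_group(sim_config(duration_s = 10, seed = i)))
  expect_error(permute_null(trajs[1], "cross_group"), ">= 2 groups")
  expect_error(permute_null(trajs, "cross_group"), "distinct")
  expect_s3_class(permute_null(trajs[[1]], "time_shift", n = 5, seed = 1),
                  "null_distribution")
})

test_that("time-shifting a constant-position pair never changes its score", {
  x <- cbind(rep(2, 1200), rep(4, 1200))       # 2 cm apart, fixed, 60 s
  y <- cbind(rep(2, 1200), rep(2, 1200))
  tr <- make_traj(x, y, fps = 20)
  nd <- permute_null(tr, "time_shift", n = 50, seed = 3)
  expect_true(all(nd$replicate_scores == 60))  # the full-length event survives
})

test_that("the empirical p-value uses the add-one estimator", {
  fake <- structure(list(replicate_scores = as.numeric(1:1000),
                         n_permutations = 1000L, method = "cross_group",
                         statistic = "duration", alpha = 0.05),
                    class = "null_distribution")
  expect_equal(exceeds_chance(2000, fake), 1 / 1001)   # beats all replicates
  expect_equal(exceeds_chance(500.5, fake), 501 / 1001)  # at the median
  expect_equal(exceeds_chance(0, fake), 1)             # below all replicates
})

test_that("null mean matches observed mean for independent groups", {
  trajs <- lapply(1:12, function(i)
    simulate_group(sim_config(attraction = 0, duration_s = 120, seed = 400 + i)))
  obs <- vapply(trajs, function(t)
    interaction_scores(detect_events(t), by_pair = FALSE)$duration_s, numeric(1))
  nd <- permute_null(trajs, "cross_group", n = 200, seed = 17)
  # independence implies exchangeability: chance scores share the scale
  expect_lt(abs(mean(nd$replicate_scores) - mean(obs)),
            3 * stats::sd(obs) / sqrt(length(obs)) + 3)
})

test_that("strong attraction exceeds its cross-group chance level", {
  trajs <- lapply(1:4, function(i)
    simulate_group(sim_config(attraction = 0.9, duration_s = 120, seed = 500 + i)))
  nd <- permute_null(trajs, "cross_group", n = 99, seed = 18)
  p <- vapply(trajs, function(t)
    exceeds_chance(interaction_scores(detect_events(t), by_pair = FALSE)$duration_s,
                   nd), numeric(1))
  expect_true(all(p <= 0.05))
})

test_that("duration calibration behaves on degenerate and easy inputs", {
  trajs <- lapply(1:4, function(i)
    simulate_group(sim_config(duration_s = 60, attraction = 0, seed = 30 + i)))
  cal <- calibrate_min_duration(trajs, grid = c(4), n = 50, seed = 5)
  expect_equal(cal$min_duration_s, 4)
  expect_type(cal$satisfied, "logical")

  # fast independent walkers in a huge arena: chance events are so rare that
  # the smallest candidate duration already suffices
  big <- arena_spec(200, 200)
  sparse <- lapply(1:4, function(i)
    simulate_group(sim_config(duration_s = 60, attraction = 0, arena = big,
                              seed = 40 + i)))
  cal2 <- calibrate_min_duration(sparse, grid = seq(0.5, 6, 0.5), n = 50, seed = 6)
  expect_true(cal2$satisfied)
  expect_lte(cal2$min_duration_s, 4)
})

test_that("the calibrated duration grows with walker density", {
  mk <- function(nf, seeds) lapply(seeds, function(i)
    simulate_group(sim_config(n_fish = nf, duration_s = 60, attraction = 0,
                              seed = i)))
  grid <- seq(0.5, 12, 0.5)
  tau2 <- calibrate_min_duration(mk(2, 51:54), grid = grid,
                                 method = "time_shift", n = 80, seed = 7)
  tau6 <- calibrate_min_duration(mk(6, 61:64), grid = grid,
                                 method = "time_shift", n = 80, seed = 8)
  expect_lte(tau2$min_duration_s, tau6$min_duration_s)
  # chance-event rates are non-increasing in the candidate duration
  expect_true(all(diff(tau6$rates$chance_events) <= 1e-12))
})
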