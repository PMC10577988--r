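# positions whose per-frame speed (cm/s) follows a prescribed series
speed_controlled_traj <- function(speed, fps = 15) {
  step <- speed / fps
  x <- cumsum(c(1, step))
  tr <- make_traj(matrix(x, ncol = 1), matrix(rep(1, length(x)), ncol = 1),
                  fps = fps)
  tr
}

test_that("saturated and empty sleep cases behave", {
  fps <- 15
  # 2-h recording spanning ZT11-ZT13: lights-off transition in the middle
  nfr <- 2 * 3600 * fps
  zt0 <- -11 * 3600 * fps                      # ZT0 was 11 h before frame 0
  still <- speed_controlled_traj(rep(0, nfr - 1), fps)
  s <- sleep_bouts(still, zt0_frame = zt0)
  expect_equal(nrow(s$bouts), 2)               # split only at the transition
  expect_equal(sort(unique(s$bouts$phase)), c("day", "night"))
  expect_equal(s$summary$sleep_min_per_h[s$summary$phase == "night"], 60,
               tolerance = 1e-3)
  expect_equal(s$summary$sleep_min_per_h[s$summary$phase == "day"], 60,
               tolerance = 1e-3)

  mover <- speed_controlled_traj(rep(2, nfr - 1), fps)
  s2 <- sleep_bouts(mover, zt0_frame = zt0)
  expect_equal(nrow(s2$bouts), 0)
  expect_equal(sum(s2$summary$sleep_min_per_h), 0)

  expect_error(sleep_bouts(still, zt0_frame = NULL), "zt0")
})

test_that("the 60-s bout boundary is sharp", {
  fps <- 15
  mk <- function(immobile_s) {
    v <- rep(2, 3000)
    v[1000 + seq_len(round(immobile_s * fps))] <- 0.1
    speed_controlled_traj(v, fps)
  }
  s59 <- sleep_bouts(mk(59), zt0_frame = 0)
  expect_equal(nrow(s59$bouts), 0)
  s60 <- sleep_bouts(mk(60), zt0_frame = 0)
  expect_equal(nrow(s60$bouts), 1)
  expect_equal(s60$bouts$duration_s, 60)
})

test_that("sleep totals are consistent and monotone in the threshold", {
  tr <- simulate_sleep_track(sim_config(fps = 15, duration_s = 3600,
                                        sleep_on_rate = 0.01,
                                        sleep_off_rate = 0.01, seed = 31))
  s <- sleep_bouts(tr, zt0_frame = 0)
  total_min <- sum(s$bouts$duration_s) / 60
  by_phase <- sum(s$summary$sleep_min_per_h * s$summary$hours_observed,
                  na.rm = TRUE)
  expect_equal(by_phase, total_min, tolerance = 1e-9)  # bouts partition sleep
  expect_lte(total_min, 60)                            # cannot exceed the hour
  expect_equal(sum(s$binned$sleep_min), total_min, tolerance = 1e-9)

  stricter <- sleep_bouts(tr, zt0_frame = 0,
                          params = sleep_params(immobility_speed = 0.25))
  expect_lte(sum(stricter$bouts$duration_s), sum(s$bouts$duration_s))
})

test_that("a known bout schedule is recovered within one frame per boundary", {
  fps <- 15
  sched <- data.frame(start_s = c(300, 900, 2000),
                      end_s = c(390, 1010, 2090))   # 90 s, 110 s, 90 s
  tr <- simulate_sleep_track(sim_config(fps = fps, duration_s = 3600, seed = 77),
                             bout_schedule = sched)
  s <- sleep_bouts(tr, zt0_frame = 0)
  expect_equal(nrow(s$bouts), 3)
  expect_equal(s$bouts$start_s, sched$start_s, tolerance = 1.01 / fps)
  expect_equal(s$bouts$end_s, sched$end_s, tolerance = 1.01 / fps)
})

test_that("vibration approaches count outside-to-inside transitions only", {
  fps <- 20
  rod <- c(5, 5)
  # oscillating fish crossing the 1.3-cm circle about the rod 7 times
  phases <- rep(c(3, 5), 7)                    # far, at-rod, far, ...
  xs <- unlist(lapply(seq_along(phases), function(i)
    rep(if (i %% 2 == 1) 9 else 5, 40)))
  tr <- make_traj(matrix(xs, ncol = 1),
                  matrix(rep(5, length(xs)), ncol = 1), fps = fps)
  out <- vab_count(tr, rod, radius = 1.3, radius_unit = "cm", assay_s = 60)
  expect_equal(out$approach_count, 7)

  # starting inside: initial residence is not an approach
  xs2 <- c(rep(5, 40), rep(9, 40), rep(5, 40), rep(9, 40), rep(5, 40))
  tr2 <- make_traj(matrix(xs2, ncol = 1), matrix(rep(5, 200), ncol = 1),
                   fps = fps)
  out2 <- vab_count(tr2, rod, radius = 1.3, radius_unit = "cm", assay_s = 60)
  expect_equal(out2$approach_count, 2)

  # never entering the circle
  far <- make_traj(matrix(rep(9, 100), ncol = 1), matrix(rep(9, 100), ncol = 1),
                   fps = fps)
  expect_equal(vab_count(far, rod, radius_unit = "cm")$approach_count, 0)

  # the printed millimetre unit shrinks the circle 10-fold
  out_mm <- vab_count(tr, rod, radius = 1.3, radius_unit = "mm", assay_s = 60)
  expect_equal(out_mm$approach_count, 7)       # fish sits exactly on the rod
  expect_equal(attr(out_mm, "radius_cm"), 0.13)

  expect_error(vab_count(tr, c(50, 50)), "inside the arena")
})
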