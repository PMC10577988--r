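test_that("pair distances enumerate all pairs and propagate gaps", {
  tr <- random_crossing_traj(50, 4, seed = 1)
  d <- pair_distances(tr)
  expect_equal(ncol(d), 6)                      # six pairs among four fish
  expect_equal(colnames(d), c("1-2", "1-3", "1-4", "2-3", "2-4", "3-4"))

  # 3-4-5 triangle: fish fixed at (0,0) and (3,4) are 5 cm apart
  x <- cbind(rep(0, 10), rep(3, 10))
  y <- cbind(rep(0, 10), rep(4, 10))
  expect_equal(unname(pair_distances(make_traj(x, y))[, 1]), rep(5, 10))

  x[4, 1] <- NA
  d2 <- pair_distances(make_traj(x, y))
  expect_true(is.na(d2[4, 1]))
  expect_false(anyNA(d2[-4, 1]))

  expect_error(pair_distances(make_traj(matrix(1, 5, 1), matrix(1, 5, 1))),
               "2 fish")
})

# two fish whose separation follows a prescribed per-frame distance series
dist_controlled_traj <- function(dist, fps = 20) {
  n <- length(dist)
  x <- cbind(rep(1, n), rep(1, n))
  y <- cbind(rep(1, n), 1 + dist)
  make_traj(x, y, fps = fps)
}

test_that("event detection honours the 4-s boundary with ties included", {
  crit <- interaction_criteria(5, 4)
  base <- rep(10, 300)

  run <- base; run[50 + seq_len(100)] <- 3     # 100 frames = 5.0 s within 3 cm
  ev <- detect_events(dist_controlled_traj(run), crit)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 5.0)
  expect_equal(ev$start_frame, 50)
  expect_equal(ev$end_frame, 150)

  ev79 <- detect_events(dist_controlled_traj(replace(base, 10 + seq_len(79), 2)), crit)
  expect_equal(nrow(ev79), 0)                  # 3.95 s misses the criterion
  ev80 <- detect_events(dist_controlled_traj(replace(base, 10 + seq_len(80), 2)), crit)
  expect_equal(ev80$duration_s, 4.0)           # exactly 4 s qualifies

  expect_equal(nrow(detect_events(dist_controlled_traj(base), crit)), 0)

  ev_all <- detect_events(dist_controlled_traj(rep(0, 6000)), crit)
  expect_equal(nrow(ev_all), 1)                # co-located fish: one 300-s event
  expect_equal(ev_all$duration_s, 300)
})

test_that("detector matches the exhaustive frame-scan oracle with gaps", {
  crit <- interaction_criteria(5, 1)           # short criterion stresses runs
  for (seed in 1:25) {
    tr <- random_crossing_traj(300, 3, seed = seed, na_frac = 0.05)
    d <- pair_distances(tr)
    ev <- detect_events(tr, crit)
    for (p in colnames(d)) {
      expected <- oracle_scan_events(d[, p], tr$fps, crit$max_distance,
                                     crit$min_duration)
      expect_equal(event_matrix(ev, p), unname(expected), ignore_attr = TRUE)
    }
  }
})

test_that("relaxing either criterion never decreases the group score", {
  for (seed in 1:10) {
    tr <- random_crossing_traj(400, 3, seed = 100 + seed)
    s0 <- interaction_scores(detect_events(tr, interaction_criteria(4, 2)),
                             by_pair = FALSE)
    s_dist <- interaction_scores(detect_events(tr, interaction_criteria(6, 2)),
                                 by_pair = FALSE)
    s_dur <- interaction_scores(detect_events(tr, interaction_criteria(4, 1)),
                                by_pair = FALSE)
    # a larger distance can merge two events into one, so only the total
    # duration is monotone in max_distance; both scores are monotone when
    # the duration criterion is relaxed
    expect_gte(s_dist$duration_s, s0$duration_s)
    expect_gte(s_dur$duration_s, s0$duration_s)
    expect_gte(s_dur$n_events, s0$n_events)
  }
})

test_that("per-pair events are disjoint and bounded by the assay length", {
  for (seed in 1:10) {
    tr <- random_crossing_traj(500, 4, seed = 200 + seed)
    ev <- detect_events(tr, interaction_criteria(5, 0.5))
    for (p in unique(ev$pair)) {
      e <- ev[ev$pair == p, ]
      e <- e[order(e$start_frame), ]
      if (nrow(e) > 1) {
        # separated by at least one non-qualifying frame
        expect_true(all(e$start_frame[-1] > e$end_frame[-nrow(e)]))
      }
    }
    expect_lte(sum(ev$duration_s), duration_frames(tr) / tr$fps * 6)
  }
})

test_that("the event raster is consistent with scores", {
  tr <- random_crossing_traj(400, 4, seed = 42)
  ev <- detect_events(tr, interaction_criteria(5, 1))
  r <- event_raster(ev)
  expect_equal(dim(r), c(6, 400))
  sc <- interaction_scores(ev)
  expect_equal(unname(rowSums(r) / tr$fps),
               sc$per_pair$duration_s[match(rownames(r), sc$per_pair$pair)])
  expect_equal(sum(sc$per_pair$duration_s), sc$duration_s)
  expect_equal(sum(sc$per_pair$n_events), sc$n_events)

  none <- detect_events(dist_controlled_traj(rep(10, 100)),
                        interaction_criteria(5, 1))
  expect_equal(interaction_scores(none, by_pair = FALSE)$duration_s, 0)
  expect_equal(interaction_scores(none, by_pair = FALSE)$n_events, 0)
  expect_true(all(event_raster(none) == 0))
})

test_that("a single event paints exactly its frames in the raster", {
  d <- rep(10, 300); d[101:200] <- 2           # frames 100..199 (0-based)
  ev <- detect_events(dist_controlled_traj(d), interaction_criteria(5, 4))
  r <- event_raster(ev)
  expect_equal(sum(r), 100)
  expect_equal(unname(which(r[1, ] == 1)), 101:200)
})

test_that("speed profile returns the constant for uniform motion", {
  # fish A cruises at 2 cm/s; fish B rides alongside within 3 cm during
  # frames 200-299 and 10 cm away otherwise, also at 2 cm/s along x
  n <- 600; fps <- 20
  a <- straight_traj_xy(n, 2, fps, x0 = 1, y0 = 2)
  yb <- rep(12, n); yb[201:300] <- 5
  x <- cbind(a[, "x"], a[, "x"])
  y <- cbind(a[, "y"], yb)
  tr <- make_traj(x, y, fps = fps, pad = 3)
  ev <- detect_events(tr, interaction_criteria(5, 4))
  expect_equal(nrow(ev), 1)
  sp <- speed_profile(tr, ev, window_s = 4)
  expect_equal(sp$before_mean[1], 2, tolerance = 1e-9)
  expect_equal(sp$during_mean[1], 2, tolerance = 1e-9)
  expect_equal(sp$after_mean[1], 2, tolerance = 1e-9)
  expect_equal(sp$out_of_event_mean[1], 2, tolerance = 1e-9)
})

test_that("speed profile handles stationary fish and fish without events", {
  x <- cbind(rep(1, 200), rep(2, 200), rep(30, 200))
  y <- cbind(rep(1, 200), rep(1, 200), rep(1, 200))
  tr <- make_traj(x, y, fps = 20)
  ev <- detect_events(tr, interaction_criteria(5, 4))
  sp <- speed_profile(tr, ev)
  expect_equal(sp$during_mean[1], 0)           # stationary pair: zero speed
  expect_equal(sp$n_events[3], 0)              # far fish has no events
  expect_true(is.na(sp$during_mean[3]))
  expect_true(is.na(sp$before_mean[3]))
})
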