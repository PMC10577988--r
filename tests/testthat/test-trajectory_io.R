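write_long_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  path
}

test_that("long-format reading counts frames and fish and converts units", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  nfr <- 7200
  df <- expand.grid(frame = 0:(nfr - 1), fish_id = 1:4)
  df$x <- runif(nrow(df), 0, 49.5)
  df$y <- runif(nrow(df), 0, 24.2)
  write_long_csv(df, tmp)
  tr <- read_trajectories(tmp, fps = 20, arena = arena_spec())
  expect_s3_class(tr, "trajectory_set")
  expect_equal(duration_frames(tr), 7200)
  expect_equal(n_fish(tr), 4)
  expect_equal(tr$x[cbind(df$frame + 1, df$fish_id)], df$x)

  # px calibration: px_per_cm 10 divides coordinates by 10
  df_px <- df
  df_px$x <- df$x * 10
  df_px$y <- df$y * 10
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_long_csv(df_px, tmp2)
  tr_px <- read_trajectories(tmp2, fps = 20,
                             arena = arena_spec(px_per_cm = 10))
  expect_equal(tr_px$x, tr$x, tolerance = 1e-12)
})

test_that("calibration is linear in px_per_cm", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(frame = rep(0:99, 2), fish_id = rep(1:2, each = 100),
                   x = runif(200, 10, 90), y = runif(200, 10, 90))
  write_long_csv(df, tmp)
  a1 <- read_trajectories(tmp, fps = 20, arena = arena_spec(10, 10, px_per_cm = 10))
  a2 <- read_trajectories(tmp, fps = 20, arena = arena_spec(5, 5, px_per_cm = 20))
  expect_equal(a1$x, 2 * a2$x, tolerance = 1e-12)
})

test_that("duplicate rows and out-of-arena coordinates are rejected", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(frame = c(0, 1, 1), fish_id = c(1, 1, 1),
                   x = c(1, 2, 3), y = c(1, 2, 3))
  write_long_csv(df, tmp)
  expect_error(read_trajectories(tmp, fps = 20, arena = arena_spec(10, 10)),
               "duplicate")

  df2 <- data.frame(frame = 0:4, fish_id = 1, x = c(1, 2, 3, 4, 25),
                    y = 1)
  tmp2 <- withr::local_tempfile(fileext = ".csv")
  write_long_csv(df2, tmp2)
  expect_error(read_trajectories(tmp2, fps = 20, arena = arena_spec(10, 10)),
               "outside")
})

test_that("missing samples are kept as gaps, not interpolated by default", {
  df <- expand.grid(frame = 0:199, fish_id = 1:2)
  df$x <- runif(400, 1, 9); df$y <- runif(400, 1, 9)
  df <- df[!(df$fish_id == 2 & df$frame %in% 100:104), ]
  tmp <- withr::local_tempfile(fileext = ".csv")
  write_long_csv(df, tmp)
  tr <- read_trajectories(tmp, fps = 20, arena = arena_spec(10, 10))
  expect_true(all(is.na(tr$x[101:105, 2])))
  expect_false(anyNA(tr$x[, 1]))

  # default gap policy: fill_gaps(max_gap_frames = 0) is the identity
  tr0 <- fill_gaps(tr, max_gap_frames = 0)
  expect_identical(tr0$x, tr$x)
  expect_equal(attr(tr0, "gap_report")$length, 5)
  expect_false(attr(tr0, "gap_report")$filled)
})

test_that("fill_gaps interpolates linearly only across short interior gaps", {
  x <- matrix(c(0, 1, NA, NA, NA, 5, 6), ncol = 1)
  y <- matrix(c(0, 2, NA, NA, NA, 10, 12), ncol = 1)
  tr <- make_traj(x, y)
  filled <- fill_gaps(tr, max_gap_frames = 5)
  expect_equal(filled$x[3:5, 1], c(2, 3, 4))   # hand-computed interpolation
  expect_equal(filled$y[3:5, 1], c(4, 6, 8))

  kept <- fill_gaps(tr, max_gap_frames = 2)    # gap of 3 > 2: preserved
  expect_true(all(is.na(kept$x[3:5, 1])))
  expect_true(attr(filled, "gap_report")$filled)
  expect_false(attr(kept, "gap_report")$filled)
})

test_that("assay_window keeps the trailing window and re-zeroes frames", {
  cfg <- sim_config(duration_s = 360, seed = 11)
  t6 <- simulate_group(cfg)
  t5 <- assay_window(t6, discard_head_s = 60, keep_s = 300)
  expect_equal(duration_frames(t5), 6000)      # last 5 min of a 6-min record
  expect_equal(t5$x[1, ], t6$x[1201, ])

  expect_identical(assay_window(t6, 0)$x, t6$x)           # identity
  expect_error(assay_window(t6, 0, keep_s = 400), "window")  # too long

  # idempotence: re-windowing the kept window changes nothing
  again <- assay_window(t5, 0, keep_s = 300)
  expect_identical(again$x, t5$x)
})

test_that("write/read round-trips coordinates to 6 decimals and metadata", {
  cfg <- sim_config(duration_s = 10, seed = 7)
  tr <- simulate_group(cfg, group_id = "rt")
  tr$x[15:18, 2] <- NA; tr$y[15:18, 2] <- NA   # include gaps
  for (fmt in c("long", "wide")) {
    tmp <- withr::local_tempfile(fileext = ".csv")
    write_trajectories(tr, tmp, format = fmt)
    back <- read_trajectories(tmp)             # fps/arena from sidecar
    expect_equal(back$fps, tr$fps)
    expect_equal(back$arena$width, tr$arena$width)
    expect_equal(back$group_id, "rt")
    expect_equal(back$x, tr$x, tolerance = 1e-6)
    expect_equal(back$y, tr$y, tolerance = 1e-6)
    expect_true(all(is.na(back$x[15:18, 2])))
  }
})

test_that("wide and long dialects load identically", {
  cfg <- sim_config(duration_s = 5, seed = 8)
  tr <- simulate_group(cfg)
  dir <- withr::local_tempdir()
  paths <- write_fixture(tr, dir, "fix")
  long <- read_trajectories(paths[["long"]])
  wide <- read_trajectories(paths[["wide"]])
  expect_equal(long$x, wide$x)
  expect_equal(long$y, wide$y)
  # long dialect has one row per frame per fish
  expect_equal(nrow(utils::read.csv(paths[["long"]])),
               duration_frames(tr) * n_fish(tr))
})
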