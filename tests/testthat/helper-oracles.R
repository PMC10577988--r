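# Independent oracles and fixture builders shared across the suite.

# Exhaustive per-frame scan for sustained-proximity events on one pair's
# distance series: a plain loop, kept deliberately independent of the rle
# machinery inside detect_events().
oracle_scan_events <- function(dist, fps, max_distance, min_duration) {
  n <- length(dist)
  out <- NULL
  run_start <- NA_integer_
  for (t in seq_len(n)) {
    ok <- !is.na(dist[t]) && dist[t] <= max_distance
    if (ok && is.na(run_start)) run_start <- t
    if (!is.na(run_start) && (!ok || t == n)) {
      run_end <- if (ok) t else t - 1L
      len <- run_end - run_start + 1L
      if (len / fps >= min_duration) {
        out <- rbind(out, c(start_frame = run_start - 1L,
                            end_frame = run_start - 1L + len))
      }
      run_start <- NA_integer_
    }
  }
  if (is.null(out)) {
    out <- matrix(integer(0), 0, 2,
                  dimnames = list(NULL, c("start_frame", "end_frame")))
  }
  out
}

# Build a trajectory_set directly from coordinate matrices, sized to fit.
make_traj <- function(x, y, fps = 20, pad = 1, group_id = "fixture") {
  x <- as.matrix(x); y <- as.matrix(y)
  w <- max(x, na.rm = TRUE) + pad
  h <- max(y, na.rm = TRUE) + pad
  trajectory_set(x, y, fps = fps, arena = arena_spec(w, h), group_id = group_id)
}

# Random jump-around trajectory that crosses the proximity threshold often;
# optionally with missing samples.
random_crossing_traj <- function(n_frames, n_fish, seed, na_frac = 0,
                                 fps = 20, side = 12) {
  set.seed(seed)
  x <- matrix(runif(n_frames * n_fish, 0, side), n_frames, n_fish)
  y <- matrix(runif(n_frames * n_fish, 0, side), n_frames, n_fish)
  # random-walk-ish smoothing so runs of proximity occur
  for (j in seq_len(n_fish)) {
    x[, j] <- pmin(pmax(filter_cumsum(x[, j], side), 0), side)
    y[, j] <- pmin(pmax(filter_cumsum(y[, j], side), 0), side)
  }
  if (na_frac > 0) {
    idx <- sample(length(x), round(na_frac * length(x)))
    x[idx] <- NA
  }
  trajectory_set(x, y, fps = fps, arena = arena_spec(side, side),
                 group_id = paste0("rand", seed))
}

# crude AR(1) smoother used only to correlate consecutive random positions
filter_cumsum <- function(v, side) {
  out <- numeric(length(v))
  out[1] <- v[1]
  for (i in 2:length(v)) out[i] <- 0.9 * out[i - 1] + 0.1 * v[i]
  out
}

# Straight-line swimmer at constant speed (cm/s), heading in radians.
straight_traj_xy <- function(n_frames, speed, fps, heading = 0,
                             x0 = 0, y0 = 0) {
  tt <- 0:(n_frames - 1)
  step <- speed / fps
  cbind(x = x0 + tt * step * cos(heading), y = y0 + tt * step * sin(heading))
}

# Sample-weighted pooled during/out speed ratio over one or more
# speed_profile() results.
pooled_speed_ratio <- function(profiles) {
  sp <- do.call(rbind, profiles)
  durw <- sum(sp$during_mean * sp$n_during, na.rm = TRUE) / sum(sp$n_during)
  outw <- sum(sp$out_of_event_mean * sp$n_out, na.rm = TRUE) / sum(sp$n_out)
  durw / outw
}

# Reflect a trajectory's y-coordinates about the arena mid-line.
mirror_y <- function(traj) {
  traj$y <- traj$arena$height - traj$y
  traj
}

# Integer start/end matrix of one pair's detected events (typed even when empty).
event_matrix <- function(ev, p) {
  m <- as.matrix(ev[ev$pair == p, c("start_frame", "end_frame")])
  storage.mode(m) <- "integer"
  unname(m)
}
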