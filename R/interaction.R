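#' Nearby-interaction detection criteria
#'
#' A sustained-proximity ("nearby interaction") event is scored when two fish
#' stay within `max_distance` cm of each other for at least `min_duration`
#' seconds.  The working criteria are 5 cm and 4 s, justified against a
#' 1000-permutation chance null (see [permute_null()] and
#' [calibrate_min_duration()]).  Ties at exactly `min_duration` are included;
#' the boundary is unit-tested and configurable.
#'
#' @param max_distance Proximity threshold in cm (> 0).
#' @param min_duration Minimum sustained duration in seconds (> 0).
#' @return An object of class `interaction_criteria`.
#' @export
interaction_criteria <- function(max_distance = 5, min_duration = 4) {
  stopifnot(is.numeric(max_distance), max_distance > 0,
            is.numeric(min_duration), min_duration > 0)
  structure(list(max_distance = max_distance, min_duration = min_duration),
            class = "interaction_criteria")
}

#' Per-frame inter-fish distances for every pair
#'
#' Euclidean distance per frame for each of the `n_fish * (n_fish - 1) / 2`
#' unordered pairs (six pairs among four fish).  A frame where either fish is
#' missing yields `NA`.
#'
#' @param traj A [trajectory_set()] with at least two fish.
#' @return Numeric matrix, frames x pairs; column names `"i-j"`; attribute
#'   `pairs` holds the 2 x P index matrix.
#' @export
pair_distances <- function(traj) {
  stopifnot(inherits(traj, "trajectory_set"))
  if (n_fish(traj) < 2) stop("pair distances need at least 2 fish", call. = FALSE)
  pr <- pair_index(n_fish(traj))
  d <- sqrt((traj$x[, pr[1, ], drop = FALSE] - traj$x[, pr[2, ], drop = FALSE])^2 +
              (traj$y[, pr[1, ], drop = FALSE] - traj$y[, pr[2, ], drop = FALSE])^2)
  colnames(d) <- pair_labels(pr, traj$fish_ids)
  attr(d, "pairs") <- pr
  d
}

#' Detect nearby-interaction events
#'
#' Finds, for every pair, the maximal runs of consecutive frames with
#' inter-fish distance at or below `crit$max_distance`; a run qualifies as an
#' event iff its length/fps is at least `crit$min_duration` seconds.  Frames
#' with a missing distance break runs (the conservative default gap policy;
#' interpolate beforehand with [fill_gaps()] to change that).  Apply
#' [assay_window()] first so events are scored on the analysed window only.
#'
#' @param traj A [trajectory_set()].
#' @param crit An [interaction_criteria()].
#' @return A data.frame of class `interaction_events` with columns `pair`,
#'   `fish_a`, `fish_b`, `start_frame` (0-based), `end_frame` (exclusive) and
#'   `duration_s = (end_frame - start_frame) / fps`, sorted by start then
#'   pair.  Attributes: `fps`, `n_frames`, `pair_names`, `criteria`.
#' @examples
#' cfg <- sim_config(attraction = 0.9, seed = 3)
#' ev <- detect_events(simulate_group(cfg))
#' interaction_scores(ev)
#' @export
detect_events <- function(traj, crit = interaction_criteria()) {
  stopifnot(inherits(traj, "trajectory_set"), inherits(crit, "interaction_criteria"))
  d <- pair_distances(traj)
  pr <- attr(d, "pairs")
  min_frames <- crit$min_duration * traj$fps
  rows <- vector("list", ncol(d))
  for (p in seq_len(ncol(d))) {
    runs <- true_runs(d[, p] <= crit$max_distance)
    if (nrow(runs) == 0) next
    keep <- runs[, "length"] >= min_frames
    runs <- runs[keep, , drop = FALSE]
    if (nrow(runs) == 0) next
    rows[[p]] <- data.frame(
      pair = colnames(d)[p],
      fish_a = traj$fish_ids[pr[1, p]],
      fish_b = traj$fish_ids[pr[2, p]],
      start_frame = runs[, "start"] - 1L,
      end_frame = runs[, "start"] - 1L + runs[, "length"],
      duration_s = runs[, "length"] / traj$fps)
  }
  ev <- if (any(!vapply(rows, is.null, logical(1)))) do.call(rbind, rows) else
    data.frame(pair = character(), fish_a = character(), fish_b = character(),
               start_frame = integer(), end_frame = integer(),
               duration_s = numeric())
  ev <- ev[order(ev$start_frame, ev$pair), , drop = FALSE]
  rownames(ev) <- NULL
  structure(ev, class = c("interaction_events", "data.frame"),
            fps = traj$fps, n_frames = duration_frames(traj),
            pair_names = colnames(d), criteria = crit)
}

#' Group-level social-affinity scores
#'
#' The group score for a 5-min assay is the total duration (s) of nearby
#' interactions and the number of events, summed over all pairs (a fish may
#' contribute through several pairs simultaneously, matching the additivity
#' of the event raster rows).
#'
#' @param events Output of [detect_events()].
#' @param by_pair Also return the per-pair breakdown.
#' @return A list of class `interaction_scores`: `duration_s`, `n_events`,
#'   and (if requested) `per_pair` data.frame.
#' @export
interaction_scores <- function(events, by_pair = TRUE) {
  stopifnot(inherits(events, "interaction_events"))
  out <- list(duration_s = sum(events$duration_s),
              n_events = nrow(events))
  if (by_pair) {
    pairs <- attr(events, "pair_names")
    per <- data.frame(
      pair = pairs,
      duration_s = vapply(pairs, function(p)
        sum(events$duration_s[events$pair == p]), numeric(1)),
      n_events = vapply(pairs, function(p)
        sum(events$pair == p), integer(1)),
      row.names = NULL)
    out$per_pair <- per
  }
  structure(out, class = "interaction_scores")
}

#' @export
print.interaction_scores <- function(x, ...) {
  cat(sprintf("<interaction_scores> total duration %.2f s over %d events\n",
              x$duration_s, x$n_events))
  if (!is.null(x$per_pair)) print(x$per_pair)
  invisible(x)
}

#' Pair-by-frame event occupancy raster
#'
#' Binary matrix (rows = pairs, columns = frames) with 1 inside detected
#' events, as drawn in event raster plots; row sums divided by fps equal the
#' per-pair interaction durations.
#'
#' @param events Output of [detect_events()].
#' @return Integer matrix, pairs x frames.
#' @export
event_raster <- function(events) {
  stopifnot(inherits(events, "interaction_events"))
  pairs <- attr(events, "pair_names")
  nf <- attr(events, "n_frames")
  m <- matrix(0L, length(pairs), nf, dimnames = list(pairs, NULL))
  for (i in seq_len(nrow(events))) {
    m[events$pair[i], (events$start_frame[i] + 1L):events$end_frame[i]] <- 1L
  }
  m
}

#' Per-frame swimming speeds
#'
#' Speed from 1-frame displacements (`displacement * fps`, cm/s), no
#' smoothing; sample `t` (0-based) covers the step from frame `t` to `t + 1`,
#' `NA` when either frame is missing.
#'
#' @param traj A [trajectory_set()].
#' @return Numeric matrix, `(duration_frames - 1)` rows x `n_fish` columns.
#' @export
swim_speeds <- function(traj) {
  stopifnot(inherits(traj, "trajectory_set"))
  nf <- duration_frames(traj)
  if (nf < 2) stop("need at least 2 frames to compute speeds", call. = FALSE)
  dx <- diff(traj$x); dy <- diff(traj$y)
  v <- sqrt(dx^2 + dy^2) * traj$fps
  colnames(v) <- traj$fish_ids
  v
}

#' Peri-event swimming-speed profile
#'
#' For each fish participating in at least one event, the mean swimming speed
#' (i) during the `window_s` seconds before its events, (ii) during the
#' events, (iii) during the `window_s` seconds after, and (iv) over the
#' out-of-event period (all frames in none of those intervals).  Where the
#' before window of one event overlaps the after window of the previous one,
#' each frame is assigned to the nearer event boundary; peri-event windows are
#' truncated at the assay bounds.  Fish with no events get `NA` for
#' (i)-(iii).
#'
#' @param traj A [trajectory_set()].
#' @param events Output of [detect_events()] on the same trajectory.
#' @param window_s Peri-event window length in seconds (default 4).
#' @return Data.frame per fish: `fish`, `before_mean`, `during_mean`,
#'   `after_mean`, `out_of_event_mean` (cm/s), `n_events`, and the sample
#'   counts `n_during`, `n_out` (for pooling across fish or groups).
#' @export
speed_profile <- function(traj, events, window_s = 4) {
  stopifnot(inherits(traj, "trajectory_set"), inherits(events, "interaction_events"),
            window_s > 0)
  v <- swim_speeds(traj)
  ns <- nrow(v)                      # speed samples, 0-based index 0..ns-1
  w <- round(window_s * traj$fps)
  out <- data.frame(fish = traj$fish_ids, before_mean = NA_real_,
                    during_mean = NA_real_, after_mean = NA_real_,
                    out_of_event_mean = NA_real_, n_events = 0L,
                    n_during = 0L, n_out = 0L)
  for (j in seq_len(n_fish(traj))) {
    id <- traj$fish_ids[j]
    ev <- events[events$fish_a == id | events$fish_b == id, , drop = FALSE]
    out$n_events[j] <- nrow(ev)
    # category per speed sample: 0 out, 1 before, 2 during, 3 after
    cat_ <- integer(ns)
    claim_dist <- rep(Inf, ns)       # distance to owning event, for overlaps
    for (i in seq_len(nrow(ev))) {
      s <- ev$start_frame[i]; e <- ev$end_frame[i]
      # during: steps fully inside the event (samples s .. e-2, 0-based)
      if (e - s >= 2) cat_[(s + 1):(e - 1)] <- 2L
      # before: samples s-w .. s-1
      b_idx <- if (s >= 1L) seq.int(max(0L, s - w), s - 1L) else integer(0)
      b_idx <- b_idx[b_idx >= 0 & b_idx < ns]
      if (length(b_idx)) {
        d2ev <- s - b_idx
        take <- cat_[b_idx + 1L] != 2L & d2ev < claim_dist[b_idx + 1L]
        cat_[b_idx[take] + 1L] <- 1L
        claim_dist[b_idx[take] + 1L] <- d2ev[take]
      }
      # after: samples e-1 .. e+w-2 (the straddle step belongs to "after")
      a_idx <- seq.int(e - 1L, e + w - 2L)
      a_idx <- a_idx[a_idx >= 0 & a_idx < ns]
      if (length(a_idx)) {
        d2ev <- a_idx - (e - 1L) + 1L
        take <- cat_[a_idx + 1L] != 2L & d2ev < claim_dist[a_idx + 1L]
        cat_[a_idx[take] + 1L] <- 3L
        claim_dist[a_idx[take] + 1L] <- d2ev[take]
      }
    }
    mean_cat <- function(k) {
      vv <- v[cat_ == k, j]
      if (all(is.na(vv)) || length(vv) == 0) NA_real_ else mean(vv, na.rm = TRUE)
    }
    if (nrow(ev) > 0) {
      out$before_mean[j] <- mean_cat(1L)
      out$during_mean[j] <- mean_cat(2L)
      out$after_mean[j] <- mean_cat(3L)
    }
    out$out_of_event_mean[j] <- mean_cat(0L)
    out$n_during[j] <- sum(cat_ == 2L & !is.na(v[, j]))
    out$n_out[j] <- sum(cat_ == 0L & !is.na(v[, j]))
  }
  out
}
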