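#' Arena geometry specification
#'
#' Describes the recording arena every trajectory is referred to: a rectangle
#' of `width` x `height` centimetres with the origin at the lower-left corner.
#' When coordinates come from the tracker in pixels, `px_per_cm` gives the
#' calibration factor applied at read time.
#'
#' @param width,height Arena size in cm. Defaults are the group assay arena
#'   (49.5 x 24.2 cm).
#' @param px_per_cm Optional pixels-per-cm calibration factor (> 0).
#' @param origin Corner convention label; only `"lower-left"` is used.
#' @return An object of class `arena_spec`.
#' @examples
#' arena_spec()            # the 49.5 x 24.2 cm group assay arena
#' arena_spec(10, 10, px_per_cm = 12.5)
#' @export
arena_spec <- function(width = 49.5, height = 24.2, px_per_cm = NULL,
                       origin = "lower-left") {
  stopifnot(is.numeric(width), length(width) == 1L, is.finite(width), width > 0,
            is.numeric(height), length(height) == 1L, is.finite(height), height > 0)
  if (!is.null(px_per_cm)) {
    stopifnot(is.numeric(px_per_cm), length(px_per_cm) == 1L,
              is.finite(px_per_cm), px_per_cm > 0)
  }
  structure(list(width = width, height = height, px_per_cm = px_per_cm,
                 origin = origin),
            class = "arena_spec")
}

#' @export
print.arena_spec <- function(x, ...) {
  cat(sprintf("<arena_spec> %.4g x %.4g cm, origin %s%s\n", x$width, x$height,
              x$origin,
              if (is.null(x$px_per_cm)) "" else
                sprintf(", %.6g px/cm", x$px_per_cm)))
  invisible(x)
}

#' Per-frame group trajectory container
#'
#' Holds aligned per-frame planar positions (cm) for every fish of one
#' recorded group.  Conventions asserted throughout the package: coordinates
#' in cm with the origin at the arena's lower-left corner, frame index
#' 0-based, analysis windows half-open `[start, end)`.  Missing samples
#' (tracking dropouts) are `NA` and are treated as run-breakers downstream
#' unless explicitly interpolated with [fill_gaps()].
#'
#' @param x,y Numeric matrices, `duration_frames` rows x `n_fish` columns,
#'   positions in cm (or px when `arena$px_per_cm` is used upstream). `NA`
#'   marks missing samples.
#' @param fps Frames per second (> 0); group assays are recorded at 20
#'   frames/s, 24-h activity assays at 15 frames/s.
#' @param arena An [arena_spec()].
#' @param group_id Label for the group.
#' @param fish_ids Optional fish labels (default `1:n_fish`).
#' @param tolerance Coordinates may exceed the arena by at most this much (cm)
#'   and are clamped; beyond it construction fails.
#' @return An object of class `trajectory_set`.
#' @seealso [read_trajectories()], [assay_window()], [fill_gaps()]
#' @export
trajectory_set <- function(x, y, fps, arena = arena_spec(),
                           group_id = "group", fish_ids = NULL,
                           tolerance = 1e-6) {
  x <- as.matrix(x); y <- as.matrix(y)
  storage.mode(x) <- "double"; storage.mode(y) <- "double"
  if (!identical(dim(x), dim(y))) stop("x and y must have identical dimensions")
  stopifnot(is.numeric(fps), length(fps) == 1L, is.finite(fps), fps > 0,
            inherits(arena, "arena_spec"), ncol(x) >= 1L)
  fish_ids <- fish_ids %||% seq_len(ncol(x))
  if (length(fish_ids) != ncol(x)) stop("fish_ids length must equal n_fish")

  bad <- function(m, lim) {
    v <- m[!is.na(m)]
    any(v < -tolerance | v > lim + tolerance)
  }
  if (bad(x, arena$width) || bad(y, arena$height)) {
    stop(sprintf(
      "coordinates outside the %g x %g cm arena beyond tolerance %g",
      arena$width, arena$height, tolerance), call. = FALSE)
  }
  x[] <- pmin(pmax(x, 0), arena$width)
  y[] <- pmin(pmax(y, 0), arena$height)
  dimnames(x) <- dimnames(y) <- list(NULL, fish_ids)

  structure(list(x = x, y = y, fps = fps, arena = arena,
                 group_id = group_id, fish_ids = fish_ids),
            class = "trajectory_set")
}

#' @rdname trajectory_set
#' @param traj A `trajectory_set`.
#' @export
n_fish <- function(traj) ncol(traj$x)

#' @rdname trajectory_set
#' @export
duration_frames <- function(traj) nrow(traj$x)

#' @export
print.trajectory_set <- function(x, ...) {
  miss <- sum(is.na(x$x) | is.na(x$y))
  cat(sprintf(
    "<trajectory_set> group '%s': %d fish x %d frames @ %g fps (%.1f s), %d missing samples\n",
    x$group_id, n_fish(x), duration_frames(x), x$fps,
    duration_frames(x) / x$fps, miss))
  print(x$arena)
  invisible(x)
}

# TRUE where a fish's sample is usable in frame f.
present <- function(traj) !is.na(traj$x) & !is.na(traj$y)

#' Restrict a trajectory to the analysed assay window
#'
#' Group assays are recorded for 6 min and only the trailing 5 min are
#' analysed; this keeps the trailing `keep_s` seconds after discarding at
#' least the first `discard_head_s` seconds, and re-zeroes frame indices.
#'
#' @param traj A [trajectory_set()].
#' @param discard_head_s Seconds discarded from the start (acclimation).
#' @param keep_s Seconds retained at the end; `NULL` keeps everything after
#'   the discarded head.
#' @return A `trajectory_set` covering the window, frame indices re-zeroed.
#'   The original start frame is attached as attribute `window_offset_frames`.
#' @examples
#' cfg <- sim_config(duration_s = 360, seed = 1)
#' t6 <- simulate_group(cfg)
#' t5 <- assay_window(t6, discard_head_s = 60, keep_s = 300)
#' duration_frames(t5) / t5$fps  # 300 s
#' @export
assay_window <- function(traj, discard_head_s, keep_s = NULL) {
  stopifnot(inherits(traj, "trajectory_set"),
            discard_head_s >= 0)
  nf <- duration_frames(traj)
  drop_frames <- round(discard_head_s * traj$fps)
  keep_frames <- if (is.null(keep_s)) nf - drop_frames else round(keep_s * traj$fps)
  if (keep_frames <= 0) stop("assay window is empty")
  if (drop_frames + keep_frames > nf) {
    stop(sprintf(
      "window longer than recording: discard %g s + keep %g s > %.4g s",
      discard_head_s, keep_frames / traj$fps, nf / traj$fps), call. = FALSE)
  }
  start <- nf - keep_frames + 1L   # trailing window, 1-based row index
  idx <- start:nf
  out <- traj
  out$x <- traj$x[idx, , drop = FALSE]
  out$y <- traj$y[idx, , drop = FALSE]
  attr(out, "window_offset_frames") <- start - 1L
  out
}

#' Interpolate short tracking dropouts
#'
#' Linearly interpolates positions across interior gaps of at most
#' `max_gap_frames` frames; longer gaps (and gaps at either end of the
#' recording) are left missing.  The default `max_gap_frames = 0` performs no
#' interpolation: downstream metrics treat missing frames as run-breakers
#' rather than inventing positions.
#'
#' @param traj A [trajectory_set()].
#' @param max_gap_frames Longest gap (frames) that may be filled.
#' @return The trajectory with gaps filled; attribute `gap_report` is a
#'   data.frame (`fish`, `start_frame` 0-based, `length`, `filled`).
#' @export
fill_gaps <- function(traj, max_gap_frames = 0L) {
  stopifnot(inherits(traj, "trajectory_set"), max_gap_frames >= 0)
  rep_rows <- list()
  nf <- duration_frames(traj)
  for (j in seq_len(n_fish(traj))) {
    miss <- is.na(traj$x[, j]) | is.na(traj$y[, j])
    runs <- true_runs(miss)
    if (nrow(runs) == 0) next
    for (k in seq_len(nrow(runs))) {
      s <- runs[k, "start"]; len <- runs[k, "length"]
      interior <- s > 1L && (s + len - 1L) < nf
      fill <- interior && len <= max_gap_frames
      if (fill) {
        i0 <- s - 1L; i1 <- s + len
        w <- seq_len(len) / (len + 1)
        traj$x[s:(s + len - 1L), j] <- traj$x[i0, j] * (1 - w) + traj$x[i1, j] * w
        traj$y[s:(s + len - 1L), j] <- traj$y[i0, j] * (1 - w) + traj$y[i1, j] * w
      }
      rep_rows[[length(rep_rows) + 1L]] <- data.frame(
        fish = traj$fish_ids[j], start_frame = s - 1L, length = len,
        filled = fill)
    }
  }
  report <- if (length(rep_rows)) do.call(rbind, rep_rows) else
    data.frame(fish = character(), start_frame = integer(),
               length = integer(), filled = logical())
  attr(traj, "gap_report") <- report
  traj
}
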