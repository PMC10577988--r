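# Fast internal scorer: total event duration (s) and event count for raw
# coordinate matrices, equivalent to detect_events() + interaction_scores()
# (the equivalence is asserted in the test suite).
score_xy <- function(x, y, fps, max_distance, min_duration) {
  pr <- pair_index(ncol(x))
  min_frames <- min_duration * fps
  dur <- 0
  cnt <- 0L
  for (p in seq_len(ncol(pr))) {
    i <- pr[1, p]; j <- pr[2, p]
    d2 <- (x[, i] - x[, j])^2 + (y[, i] - y[, j])^2
    runs <- true_runs(d2 <= max_distance^2)
    if (nrow(runs) == 0) next
    ok <- runs[, "length"] >= min_frames
    dur <- dur + sum(runs[ok, "length"]) / fps
    cnt <- cnt + sum(ok)
  }
  c(duration = dur, count = cnt)
}

#' Permutation null distribution of group affinity scores
#'
#' Builds the chance distribution of group interaction scores used to justify
#' the proximity/duration criteria and to test whether an observed group's
#' affinity exceeds chance.  Two null constructions are provided because the
#' published description (1000 trajectory permutations) does not pin down the
#' scheme; outputs are labelled with the method used:
#'
#' * `cross_group` (default with several groups): each replicate assembles a
#'   virtual group whose members are drawn from distinct real groups (one
#'   randomly chosen fish per sampled group) - the standard chance-encounter
#'   null for shoaling assays.  Requires at least `n_fish` groups with equal
#'   fps, arena and length.
#' * `time_shift`: each replicate circularly shifts every fish's series of one
#'   group by an independent uniform offset of at least
#'   `min_duration * fps` frames (avoiding near-identity permutations); this
#'   preserves each fish's marginal path statistics.
#'
#' Each replicate is scored with the working criteria via the same
#' detector as [detect_events()].  Reproducible given `seed`.
#'
#' @param trajs A [trajectory_set()] or list of them (all equal fps/arena/
#'   duration for `cross_group`).
#' @param method `"cross_group"` or `"time_shift"`.
#' @param n Number of permutation replicates (default 1000).
#' @param seed Integer seed.
#' @param criteria An [interaction_criteria()].
#' @param statistic Group score to record: total `"duration"` (s) or event
#'   `"count"`.
#' @param alpha Tail probability stored for downstream calibration reports.
#' @return An object of class `null_distribution`: `replicate_scores`,
#'   `n_permutations`, `method`, `statistic`, `criteria`, `alpha`.
#' @seealso [exceeds_chance()], [calibrate_min_duration()]
#' @export
permute_null <- function(trajs, method = c("cross_group", "time_shift"),
                         n = 1000, seed = 1,
                         criteria = interaction_criteria(),
                         statistic = c("duration", "count"),
                         alpha = 0.05) {
  method <- match.arg(method)
  statistic <- match.arg(statistic)
  if (inherits(trajs, "trajectory_set")) trajs <- list(trajs)
  stopifnot(length(trajs) >= 1, n >= 1, alpha > 0, alpha < 1)
  lapply(trajs, function(t) stopifnot(inherits(t, "trajectory_set")))
  fps <- trajs[[1]]$fps
  nf <- n_fish(trajs[[1]])
  len <- duration_frames(trajs[[1]])

  scores <- with_seed(seed, {
    if (method == "cross_group") {
      if (length(trajs) < 2) {
        stop("cross_group needs >= 2 groups; use method = 'time_shift' for one",
             call. = FALSE)
      }
      if (length(trajs) < nf) {
        stop(sprintf(paste0(
          "cross_group assembles each virtual-group member from a distinct ",
          "real group: need >= %d groups, got %d; use method = 'time_shift'"),
          nf, length(trajs)), call. = FALSE)
      }
      same <- vapply(trajs, function(t)
        t$fps == fps && n_fish(t) == nf && duration_frames(t) == len, logical(1))
      if (!all(same)) stop("groups must share fps, n_fish and duration", call. = FALSE)
      vapply(seq_len(n), function(r) {
        gs <- sample.int(length(trajs), nf)           # distinct source groups
        fs <- sample.int(nf, nf, replace = TRUE)      # one fish from each
        x <- vapply(seq_len(nf), function(k) trajs[[gs[k]]]$x[, fs[k]],
                    numeric(len))
        y <- vapply(seq_len(nf), function(k) trajs[[gs[k]]]$y[, fs[k]],
                    numeric(len))
        score_xy(x, y, fps, criteria$max_distance, criteria$min_duration)[[statistic]]
      }, numeric(1))
    } else {
      if (length(trajs) != 1) {
        stop("time_shift permutes a single group", call. = FALSE)
      }
      tr <- trajs[[1]]
      min_off <- min(ceiling(criteria$min_duration * fps), floor(len / 2))
      vapply(seq_len(n), function(r) {
        x <- tr$x; y <- tr$y
        for (k in seq_len(nf)) {
          off <- sample(min_off:(len - min_off), 1L)
          idx <- c((off + 1L):len, 1L:off)
          x[, k] <- x[idx, k]; y[, k] <- y[idx, k]
        }
        score_xy(x, y, fps, criteria$max_distance, criteria$min_duration)[[statistic]]
      }, numeric(1))
    }
  })
  structure(list(replicate_scores = scores, n_permutations = n,
                 method = method, statistic = statistic,
                 criteria = criteria, alpha = alpha),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  q <- stats::quantile(x$replicate_scores, c(0.5, 0.95, 0.99))
  cat(sprintf(
    "<null_distribution> %s, %d replicates of %s score: median %.3g, q95 %.3g, q99 %.3g\n",
    x$method, x$n_permutations, x$statistic, q[1], q[2], q[3]))
  invisible(x)
}

#' Empirical p-value against a permutation null
#'
#' Add-one empirical tail probability
#' `p = (1 + #\{replicate >= observed\}) / (n + 1)`, never exactly zero.
#'
#' @param observed Observed group score (same statistic as the null).
#' @param null A [permute_null()] result.
#' @return The empirical p-value.
#' @export
exceeds_chance <- function(observed, null) {
  stopifnot(inherits(null, "null_distribution"),
            is.numeric(observed), length(observed) == 1L)
  (1 + sum(null$replicate_scores >= observed)) / (null$n_permutations + 1)
}

#' Calibrate the minimum event duration against chance
#'
#' Reconstructs the criterion-calibration step: from the permutation null it
#' computes, for every candidate duration in `grid`, the expected per-group
#' number of chance proximity runs at least that long, and returns the
#' smallest duration whose expected chance-event count is at most `alpha`.
#' If no grid value satisfies the criterion the largest is returned flagged
#' `satisfied = FALSE`.
#'
#' @param trajs Groups passed to [permute_null()].
#' @param max_distance Proximity threshold in cm (held fixed; only the
#'   duration criterion is calibrated).
#' @param alpha Acceptable expected chance-event count per group.
#' @param grid Increasing candidate durations (s).
#' @param method,n,seed Passed to the permutation engine.
#' @return List of class `duration_calibration`: `min_duration_s`,
#'   `satisfied`, `rates` (data.frame duration_s, chance_events), and the
#'   pooled `null_durations` (s) of all chance proximity runs.
#' @export
calibrate_min_duration <- function(trajs, max_distance = 5, alpha = 0.05,
                                   grid = seq(0.5, 10, by = 0.5),
                                   method = c("cross_group", "time_shift"),
                                   n = 1000, seed = 1) {
  method <- match.arg(method)
  stopifnot(length(grid) >= 1, !is.unsorted(grid, strictly = TRUE), all(grid > 0))
  if (inherits(trajs, "trajectory_set")) trajs <- list(trajs)
  fps <- trajs[[1]]$fps
  # Null of *all* proximity run durations: score with a 1-frame minimum.
  crit1 <- interaction_criteria(max_distance, 1 / fps)
  nf <- n_fish(trajs[[1]])
  len <- duration_frames(trajs[[1]])

  durations <- with_seed(seed, {
    reps <- vector("list", n)
    for (r in seq_len(n)) {
      if (method == "cross_group") {
        if (length(trajs) < nf) {
          stop(sprintf("cross_group calibration needs >= %d groups", nf),
               call. = FALSE)
        }
        gs <- sample.int(length(trajs), nf)
        fs <- sample.int(nf, nf, replace = TRUE)
        x <- vapply(seq_len(nf), function(k) trajs[[gs[k]]]$x[, fs[k]], numeric(len))
        y <- vapply(seq_len(nf), function(k) trajs[[gs[k]]]$y[, fs[k]], numeric(len))
      } else {
        tr <- trajs[[sample.int(length(trajs), 1L)]]
        x <- tr$x; y <- tr$y
        min_off <- min(ceiling(grid[length(grid)] * fps), floor(len / 2))
        for (k in seq_len(nf)) {
          off <- sample(min_off:(len - min_off), 1L)
          idx <- c((off + 1L):len, 1L:off)
          x[, k] <- x[idx, k]; y[, k] <- y[idx, k]
        }
      }
      pr <- pair_index(ncol(x))
      runs_s <- numeric(0)
      for (p in seq_len(ncol(pr))) {
        d2 <- (x[, pr[1, p]] - x[, pr[2, p]])^2 + (y[, pr[1, p]] - y[, pr[2, p]])^2
        rr <- true_runs(d2 <= max_distance^2)
        if (nrow(rr)) runs_s <- c(runs_s, rr[, "length"] / fps)
      }
      reps[[r]] <- runs_s
    }
    reps
  })

  rates <- vapply(grid, function(tau)
    mean(vapply(durations, function(d) sum(d >= tau), numeric(1))), numeric(1))
  ok <- which(rates <= alpha)
  satisfied <- length(ok) > 0
  tau <- if (satisfied) grid[ok[1]] else grid[length(grid)]
  structure(list(min_duration_s = tau, satisfied = satisfied,
                 rates = data.frame(duration_s = grid, chance_events = rates),
                 null_durations = sort(unlist(durations)),
                 alpha = alpha, method = method, n_permutations = n),
            class = "duration_calibration")
}

#' @export
print.duration_calibration <- function(x, ...) {
  cat(sprintf(
    "<duration_calibration> min duration %.2f s (%s; expected chance events <= %g %s)\n",
    x$min_duration_s, x$method, x$alpha,
    if (x$satisfied) "satisfied" else "NOT satisfied at any grid value"))
  invisible(x)
}
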