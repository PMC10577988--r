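#' Simulation configuration for synthetic fish-group trajectories
#'
#' Parameterises the correlated-random-walk group simulator that stands in
#' for the archived tracking videos.  Defaults emulate the group assay: four
#' fish at 20 frames/s in the 49.5 x 24.2 cm arena, 5-min records.  Movement
#' is a heading random walk with reflective walls; a group-level social state
#' (Markov on/off switching) picks a leader-follower dyad at onset, steers the
#' follower toward the leader with weight `attraction`, and multiplies both
#' members' speeds by `social_speed_factor` while they are within
#' `prox_radius` (fish slow down to interact).  A per-window turn kick with
#' left probability `left_bias` injects lateral turning bias.  For 24-h sleep
#' assays at 15 frames/s, two-state active/quiescent dynamics are governed by
#' `sleep_on_rate`/`sleep_off_rate` (see [simulate_sleep_track()]).
#'
#' @param n_fish Group size (default 4).
#' @param fps Frames per second (default 20; sleep assays use 15).
#' @param duration_s Recording length in seconds (default 300).
#' @param arena An [arena_spec()].
#' @param mean_speed,sd_speed Per-frame speed draw, cm/s (truncated at 0).
#' @param heading_sd Wrapped-noise spread of the heading walk, rad/frame.
#' @param attraction Social gain in \[0, 1\]: scales the follower's
#'   per-frame heading blend toward its leader (0 = independent fish); the
#'   effective per-frame blend weight is `attraction * steer_gain`, so the
#'   attraction axis maps onto a graded tracking fidelity instead of
#'   saturating near perfect pursuit.
#' @param steer_gain Per-frame steering gain ceiling (default 0.1 at the
#'   20 frames/s assay rate).
#' @param social_on_rate,social_off_rate Markov switching rates of the social
#'   state, per second.
#' @param social_speed_factor Speed multiplier (< 1) applied to the dyad
#'   while interacting within `prox_radius`.
#' @param prox_radius Distance (cm) separating the "approach" and "interact"
#'   regimes of a social bout; matches the 5-cm interaction criterion.
#' @param slow_radius Distance (cm) within which the interacting dyad swims
#'   at `social_speed_factor` of its drawn speed (default 5, the detection
#'   radius).
#' @param chase_boost Follower speed multiplier while approaching (social
#'   state on, still beyond `prox_radius`).
#' @param left_bias Probability that a turn kick goes left (default 0.5,
#'   balanced).
#' @param turn_angle Magnitude of each turn kick, radians.
#' @param turn_every Frames between turn kicks (default 5, the 0.25-s turning
#'   cadence).
#' @param sleep_on_rate,sleep_off_rate Active-to-quiescent and
#'   quiescent-to-active rates, per second (24-h mode).
#' @param quiescent_speed Speed scale (cm/s) of quiescent jitter, well below
#'   the immobility threshold.
#' @param seed Integer seed; all randomness flows from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_fish = 4, fps = 20, duration_s = 300,
                       arena = arena_spec(), mean_speed = 6, sd_speed = 1.5,
                       heading_sd = 0.3, attraction = 0.6,
                       social_on_rate = 0.05, social_off_rate = 0.02,
                       social_speed_factor = 0.5, prox_radius = 5,
                       slow_radius = 5, steer_gain = 0.1, chase_boost = 1.5,
                       left_bias = 0.5, turn_angle = 0.4,
                       turn_every = 5, sleep_on_rate = 0.005,
                       sleep_off_rate = 0.01, quiescent_speed = 0.05,
                       seed = 1) {
  cfg <- list(n_fish = n_fish, fps = fps, duration_s = duration_s,
              arena = arena, mean_speed = mean_speed, sd_speed = sd_speed,
              heading_sd = heading_sd, attraction = attraction,
              social_on_rate = social_on_rate, social_off_rate = social_off_rate,
              social_speed_factor = social_speed_factor,
              prox_radius = prox_radius, slow_radius = slow_radius,
              steer_gain = steer_gain,
              chase_boost = chase_boost,
              left_bias = left_bias, turn_angle = turn_angle,
              turn_every = turn_every, sleep_on_rate = sleep_on_rate,
              sleep_off_rate = sleep_off_rate, quiescent_speed = quiescent_speed,
              seed = seed)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    stopifnot(n_fish >= 1, fps > 0, duration_s > 0,
              inherits(arena, "arena_spec"),
              mean_speed >= 0, sd_speed >= 0, heading_sd >= 0,
              attraction >= 0, attraction <= 1,
              social_on_rate >= 0, social_off_rate >= 0,
              social_speed_factor > 0, social_speed_factor <= 1,
              prox_radius > 0, slow_radius > 0, steer_gain > 0,
              steer_gain <= 1, chase_boost > 0,
              left_bias >= 0, left_bias <= 1, turn_angle >= 0, turn_every >= 1,
              sleep_on_rate >= 0, sleep_off_rate >= 0, quiescent_speed >= 0)
  })
  invisible(cfg)
}

#' Simulate a fish-group trajectory with known social structure
#'
#' Runs the group simulator described in [sim_config()] and returns the
#' trajectory together with its ground truth (social bout intervals with the
#' leader/follower identities), so detector output can be validated against
#' what was injected.  With `attraction = 0` the social machinery is inert
#' and the fish are mutually independent correlated random walks (the
#' chance-encounter reference condition).  Walls reflect
#' specularly and the heading is re-randomised (pointing inward) on contact
#' to avoid corner trapping.  Fully reproducible given `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param group_id Label for the simulated group.
#' @return A [trajectory_set()]; attribute `ground_truth` is a list with
#'   `social_bouts` (data.frame `start_frame`, `end_frame` half-open,
#'   `leader`, `follower`) and `config`.
#' @export
simulate_group <- function(cfg, group_id = "sim") {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  nfr <- round(cfg$duration_s * cfg$fps)
  k <- cfg$n_fish
  W <- cfg$arena$width; H <- cfg$arena$height

  res <- with_seed(cfg$seed, {
    x <- matrix(NA_real_, nfr, k); y <- matrix(NA_real_, nfr, k)
    x[1, ] <- stats::runif(k, 0.1 * W, 0.9 * W)
    y[1, ] <- stats::runif(k, 0.1 * H, 0.9 * H)
    theta <- stats::runif(k, -pi, pi)
    # pre-drawn per-frame noise; turn kicks live on the turning cadence only
    sp_all <- matrix(pmax(stats::rnorm(nfr * k, cfg$mean_speed, cfg$sd_speed), 0),
                     nfr, k)
    hd_noise <- matrix(stats::rnorm(nfr * k, 0, cfg$heading_sd), nfr, k)
    kick_mat <- matrix((2 * (stats::runif(nfr * k) < cfg$left_bias) - 1) *
                         cfg$turn_angle, nfr, k)
    kick_mat[((seq_len(nfr) - 1L) %% cfg$turn_every) != 0L, ] <- 0
    u_state <- stats::runif(nfr)

    p_on <- cfg$social_on_rate / cfg$fps
    p_off <- cfg$social_off_rate / cfg$fps
    slow_mat <- matrix(FALSE, nfr, k)   # ground truth: slowdown applied
    social <- FALSE; leader <- NA_integer_; follower <- NA_integer_
    bout_start <- NA_integer_
    bouts <- list()

    # the social machinery engages only for a positive attraction gain:
    # attraction 0 means mutually independent walks (the chance-level null)
    socialable <- k >= 2 && cfg$attraction > 0

    for (t in 2:nfr) {
      # social state switching (group level, one dyad at a time)
      if (socialable) {
        if (!social && u_state[t] < p_on) {
          social <- TRUE
          dy <- sample.int(k, 2L)
          leader <- dy[1]; follower <- dy[2]
          bout_start <- t - 1L           # 0-based frame
        } else if (social && u_state[t] < p_off) {
          social <- FALSE
          bouts[[length(bouts) + 1L]] <- c(bout_start, t - 1L, leader, follower)
          # the dyad parts ways: both members head off independently
          theta[c(leader, follower)] <- stats::runif(2, -pi, pi)
          leader <- NA_integer_; follower <- NA_integer_
        }
      }

      # heading update: turn kick at the turning cadence + wrapped noise
      theta <- wrap_angle(theta + kick_mat[t, ] + hd_noise[t, ])

      sp <- sp_all[t, ]
      if (social) {
        d2 <- (x[t - 1, leader] - x[t - 1, follower])^2 +
          (y[t - 1, leader] - y[t - 1, follower])^2
        bearing <- atan2(y[t - 1, leader] - y[t - 1, follower],
                         x[t - 1, leader] - x[t - 1, follower])
        w_steer <- cfg$attraction * cfg$steer_gain
        theta[follower] <- wrap_angle(
          theta[follower] + w_steer * wrap_angle(bearing - theta[follower]))
        if (d2 <= cfg$slow_radius^2) {
          # the interacting dyad slows down to express affinity
          sp[c(leader, follower)] <- sp[c(leader, follower)] * cfg$social_speed_factor
          slow_mat[t - 1L, c(leader, follower)] <- TRUE
        } else {
          sp[follower] <- sp[follower] * cfg$chase_boost
        }
      }

      nx <- x[t - 1, ] + sp / cfg$fps * cos(theta)
      ny <- y[t - 1, ] + sp / cfg$fps * sin(theta)
      hit <- which(nx < 0 | nx > W | ny < 0 | ny > H)
      if (length(hit)) {
        # specular reflection, clamped against pathological double bounces
        nx[hit] <- pmin(pmax(abs(nx[hit]) %% (2 * W), 0), 2 * W)
        nx[hit] <- ifelse(nx[hit] > W, 2 * W - nx[hit], nx[hit])
        ny[hit] <- pmin(pmax(abs(ny[hit]) %% (2 * H), 0), 2 * H)
        ny[hit] <- ifelse(ny[hit] > H, 2 * H - ny[hit], ny[hit])
        # re-randomise heading inward for wall-contact fish
        for (i in hit) {
          inward <- atan2(H / 2 - ny[i], W / 2 - nx[i])
          theta[i] <- wrap_angle(inward + stats::runif(1, -pi / 2, pi / 2))
        }
      }
      x[t, ] <- nx; y[t, ] <- ny
    }
    if (social) bouts[[length(bouts) + 1L]] <- c(bout_start, nfr, leader, follower)
    list(x = x, y = y, bouts = bouts, slow = slow_mat)
  })

  gt_bouts <- if (length(res$bouts)) {
    m <- do.call(rbind, res$bouts)
    data.frame(start_frame = m[, 1], end_frame = m[, 2],
               leader = m[, 3], follower = m[, 4])
  } else {
    data.frame(start_frame = integer(), end_frame = integer(),
               leader = integer(), follower = integer())
  }
  traj <- trajectory_set(res$x, res$y, fps = cfg$fps, arena = cfg$arena,
                         group_id = group_id)
  attr(traj, "ground_truth") <- list(social_bouts = gt_bouts,
                                     slow = res$slow, config = cfg)
  traj
}

#' Simulate a 24-h single-fish activity track with sleep bouts
#'
#' Two-state active/quiescent semi-Markov process at the sleep-assay frame
#' rate (15 frames/s by default in [sim_config()] terms, pass
#' `sim_config(fps = 15, duration_s = 86400, ...)`): active dwell times are
#' exponential with rate `sleep_on_rate`, quiescent dwells with rate
#' `sleep_off_rate`.  Active frames move at the speed model; quiescent frames
#' jitter at `quiescent_speed`, below the immobility threshold.  Positions
#' are a folded (reflected) random walk inside the arena.  A fixed
#' `bout_schedule` can override the stochastic states to inject a known
#' ground truth.
#'
#' @param cfg A [sim_config()] (use `fps = 15` and the intended duration).
#' @param bout_schedule Optional data.frame `start_s`, `end_s` of quiescent
#'   intervals replacing the stochastic state sequence.
#' @param group_id Label.
#' @return A single-fish [trajectory_set()]; attribute `ground_truth` holds
#'   `quiescent_bouts` (data.frame `start_s`, `end_s`) and `config`.
#' @export
simulate_sleep_track <- function(cfg, bout_schedule = NULL, group_id = "sleep_sim") {
  stopifnot(inherits(cfg, "sim_config"))
  nfr <- round(cfg$duration_s * cfg$fps)
  W <- cfg$arena$width; H <- cfg$arena$height

  res <- with_seed(cfg$seed, {
    quiescent <- logical(nfr)
    if (!is.null(bout_schedule)) {
      stopifnot(all(c("start_s", "end_s") %in% names(bout_schedule)))
      for (i in seq_len(nrow(bout_schedule))) {
        a <- round(bout_schedule$start_s[i] * cfg$fps) + 1L
        b <- round(bout_schedule$end_s[i] * cfg$fps)
        quiescent[a:b] <- TRUE
      }
      sched <- data.frame(start_s = bout_schedule$start_s,
                          end_s = bout_schedule$end_s)
    } else if (cfg$sleep_on_rate > 0) {
      t_frame <- 1L
      state_q <- FALSE
      starts <- numeric(0); ends <- numeric(0)
      while (t_frame <= nfr) {
        rate <- if (state_q) cfg$sleep_off_rate else cfg$sleep_on_rate
        dwell <- max(1L, round(stats::rexp(1, rate) * cfg$fps))
        e <- min(nfr, t_frame + dwell - 1L)
        if (state_q) {
          quiescent[t_frame:e] <- TRUE
          starts <- c(starts, (t_frame - 1L) / cfg$fps)
          ends <- c(ends, e / cfg$fps)
        }
        t_frame <- e + 1L
        state_q <- !state_q
      }
      sched <- data.frame(start_s = starts, end_s = ends)
    } else {
      sched <- data.frame(start_s = numeric(), end_s = numeric())
    }

    sp <- pmax(stats::rnorm(nfr, cfg$mean_speed, cfg$sd_speed), 0)
    sp[quiescent] <- abs(stats::rnorm(sum(quiescent), 0, cfg$quiescent_speed))
    ang <- stats::runif(nfr, -pi, pi)
    step <- sp / cfg$fps
    # folded random walk keeps positions in the arena; folding is
    # 1-Lipschitz so measured speeds never exceed generated speeds
    fold <- function(z, lim) {
      z <- z %% (2 * lim)
      ifelse(z <= lim, z, 2 * lim - z)
    }
    x <- fold(W / 2 + cumsum(step * cos(ang)), W)
    y <- fold(H / 2 + cumsum(step * sin(ang)), H)
    list(x = x, y = y, sched = sched)
  })

  traj <- trajectory_set(matrix(res$x, ncol = 1), matrix(res$y, ncol = 1),
                         fps = cfg$fps, arena = cfg$arena, group_id = group_id)
  attr(traj, "ground_truth") <- list(quiescent_bouts = res$sched, config = cfg)
  traj
}

#' Simulate a pure turning walk with known left-turn probability
#'
#' Minimal fixture for the turning-bias estimator: a single fish advances at
#' constant speed and, once per `window_frames` block, turns left with
#' probability `left_prob` (else right) by `turn_angle` radians, with no
#' heading noise and no walls (the arena is made large enough to contain the
#' path).  The expected turning-bias ratio is
#' `max(p, 1 - p) / min(p, 1 - p)`.
#'
#' @param n_windows Number of turn decisions.
#' @param left_prob Probability of a left (anticlockwise) turn.
#' @param window_frames Frames per block (default 5).
#' @param fps Frame rate (default 20).
#' @param speed Speed in cm/s.
#' @param turn_angle Turn magnitude, radians.
#' @param seed Integer seed.
#' @return A single-fish [trajectory_set()] in an unbounded-equivalent arena;
#'   attribute `ground_truth` holds the injected turn directions.
#' @export
simulate_turning_walk <- function(n_windows, left_prob, window_frames = 5L,
                                  fps = 20, speed = 4, turn_angle = 0.4,
                                  seed = 1) {
  stopifnot(n_windows >= 2, left_prob >= 0, left_prob <= 1)
  w <- as.integer(window_frames)
  res <- with_seed(seed, {
    left <- stats::runif(n_windows) < left_prob
    dtheta <- ifelse(left, turn_angle, -turn_angle)
    theta_w <- cumsum(dtheta)             # heading during each window
    theta <- rep(theta_w, each = w)
    step <- speed / fps
    x <- cumsum(c(0, step * cos(theta)))
    y <- cumsum(c(0, step * sin(theta)))
    list(x = x, y = y, left = left)
  })
  span <- 2 * (max(abs(res$x), abs(res$y)) + 1)
  arena <- arena_spec(span, span)
  traj <- trajectory_set(matrix(res$x + span / 2, ncol = 1),
                         matrix(res$y + span / 2, ncol = 1),
                         fps = fps, arena = arena, group_id = "turning_walk")
  attr(traj, "ground_truth") <- list(left = res$left)
  traj
}
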