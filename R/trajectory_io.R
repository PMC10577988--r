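#' Read a tracker-output trajectory table
#'
#' Reads per-frame X-Y coordinates for a group of fish from a delimited text
#' file (the post-tracking coordinate export; video decoding and identity
#' tracking are upstream of this package).  Two dialects are supported:
#'
#' * `long` - columns `frame`, `fish_id`, `x`, `y`, one row per frame per
#'   fish; frames or coordinates may be missing.
#' * `wide` - columns `frame`, `x1`, `y1`, `x2`, `y2`, ...
#'
#' Coordinates are converted to cm via `arena$px_per_cm` when present, frames
#' are sorted and aligned on a common 0-based index, and missing samples are
#' preserved as explicit `NA` gaps (no interpolation; see [fill_gaps()]).
#'
#' When `fps` or `arena` is `NULL` they are taken from a JSON sidecar
#' `<path-sans-ext>.json` as written by [write_trajectories()].
#'
#' @param path Path to a CSV (comma) or TSV/TXT (tab) file.
#' @param fps Frames per second; `NULL` to read from the sidecar.
#' @param arena An [arena_spec()]; `NULL` to read from the sidecar.
#' @param format `"auto"` (detect from header), `"long"` or `"wide"`.
#' @param group_id Group label; defaults to the file name.
#' @param tolerance Allowed out-of-arena excursion (cm) before rejection.
#' @return A [trajectory_set()].
#' @export
read_trajectories <- function(path, fps = NULL, arena = NULL,
                              format = c("auto", "long", "wide"),
                              group_id = NULL, tolerance = 0.1) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)

  meta <- read_sidecar(path)
  fps <- fps %||% meta$fps
  arena <- arena %||% meta$arena
  if (is.null(fps)) stop("fps not given and no sidecar found", call. = FALSE)
  if (is.null(arena)) stop("arena not given and no sidecar found", call. = FALSE)
  group_id <- group_id %||% meta$group_id %||%
    tools::file_path_sans_ext(basename(path))

  if (format == "auto") {
    format <- if ("fish_id" %in% names(tab)) "long" else "wide"
  }
  if (!"frame" %in% names(tab)) stop("input lacks a 'frame' column", call. = FALSE)

  if (format == "long") {
    need <- c("frame", "fish_id", "x", "y")
    if (!all(need %in% names(tab))) {
      stop("long format needs columns frame, fish_id, x, y", call. = FALSE)
    }
    if (anyDuplicated(tab[, c("frame", "fish_id")])) {
      dup <- tab[duplicated(tab[, c("frame", "fish_id")]), , drop = FALSE]
      stop(sprintf("duplicate (frame, fish_id) rows, first at frame %s fish %s",
                   dup$frame[1], dup$fish_id[1]), call. = FALSE)
    }
    fish <- sort(unique(tab$fish_id))
    frames <- seq(min(tab$frame), max(tab$frame))
    nf <- length(frames)
    x <- matrix(NA_real_, nf, length(fish))
    y <- matrix(NA_real_, nf, length(fish))
    ri <- match(tab$frame, frames)
    ci <- match(tab$fish_id, fish)
    x[cbind(ri, ci)] <- tab$x
    y[cbind(ri, ci)] <- tab$y
    fish_ids <- fish
  } else {
    xcols <- grep("^x[0-9]+$", names(tab), value = TRUE)
    ycols <- grep("^y[0-9]+$", names(tab), value = TRUE)
    k <- sub("^x", "", xcols)
    if (length(xcols) == 0 || !setequal(paste0("y", k), ycols)) {
      stop("wide format needs paired columns x1,y1,x2,y2,...", call. = FALSE)
    }
    if (anyDuplicated(tab$frame)) stop("duplicate frame rows", call. = FALSE)
    ord <- order(as.integer(k))
    k <- k[ord]
    frames <- seq(min(tab$frame), max(tab$frame))
    ri <- match(tab$frame, frames)
    nf <- length(frames)
    x <- matrix(NA_real_, nf, length(k))
    y <- matrix(NA_real_, nf, length(k))
    for (j in seq_along(k)) {
      x[ri, j] <- tab[[paste0("x", k[j])]]
      y[ri, j] <- tab[[paste0("y", k[j])]]
    }
    fish_ids <- as.integer(k)
  }

  if (!is.null(arena$px_per_cm)) {
    x <- x / arena$px_per_cm
    y <- y / arena$px_per_cm
  }
  oob <- sum(x < -tolerance | x > arena$width + tolerance |
               y < -tolerance | y > arena$height + tolerance, na.rm = TRUE)
  if (oob > 0) {
    stop(sprintf(
      "%d samples fall outside the %g x %g cm arena beyond %g cm tolerance",
      oob, arena$width, arena$height, tolerance), call. = FALSE)
  }
  trajectory_set(x, y, fps = fps, arena = arena, group_id = group_id,
                 fish_ids = fish_ids, tolerance = tolerance)
}

read_sidecar <- function(path) {
  sc <- paste0(tools::file_path_sans_ext(path), ".json")
  if (!file.exists(sc)) return(list())
  m <- jsonlite::read_json(sc, simplifyVector = TRUE)
  out <- list(fps = m$fps, group_id = m$group_id)
  if (!is.null(m$arena)) {
    out$arena <- arena_spec(m$arena$width, m$arena$height,
                            px_per_cm = m$arena$px_per_cm,
                            origin = m$arena$origin %||% "lower-left")
  }
  out
}

#' Write a trajectory table and its metadata sidecar
#'
#' Writes a [trajectory_set()] back to a delimited text file in the long or
#' wide dialect, with coordinates printed at 6 decimals (cm), plus a JSON
#' sidecar `<path-sans-ext>.json` carrying fps, arena and group id so that
#' [read_trajectories()] round-trips coordinates and metadata.
#'
#' @param traj A [trajectory_set()].
#' @param path Output file (`.csv` comma, otherwise tab).
#' @param format `"long"` or `"wide"`.
#' @param digits Printed coordinate decimals.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path, format = c("long", "wide"),
                               digits = 6) {
  format <- match.arg(format)
  stopifnot(inherits(traj, "trajectory_set"))
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  fmt <- function(v) ifelse(is.na(v), NA, sprintf(paste0("%.", digits, "f"), v))
  nf <- duration_frames(traj)
  if (format == "long") {
    df <- data.frame(
      frame = rep(0:(nf - 1L), times = n_fish(traj)),
      fish_id = rep(traj$fish_ids, each = nf),
      x = fmt(as.vector(traj$x)),
      y = fmt(as.vector(traj$y)))
    df <- df[order(df$frame, df$fish_id), ]
  } else {
    df <- data.frame(frame = 0:(nf - 1L))
    for (j in seq_len(n_fish(traj))) {
      df[[paste0("x", j)]] <- fmt(traj$x[, j])
      df[[paste0("y", j)]] <- fmt(traj$y[, j])
    }
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  sidecar <- list(
    fps = traj$fps, group_id = traj$group_id, format = format,
    arena = list(width = traj$arena$width, height = traj$arena$height,
                 px_per_cm = traj$arena$px_per_cm,
                 origin = traj$arena$origin))
  jsonlite::write_json(sidecar, paste0(tools::file_path_sans_ext(path), ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Emit a tracker-format fixture in both dialects
#'
#' Convenience wrapper used by the simulator: writes `<basename>_long.csv`
#' and `<basename>_wide.csv` (each with its JSON sidecar) under `dir`.
#'
#' @param traj A [trajectory_set()].
#' @param dir Output directory (created if needed).
#' @param basename File stem.
#' @return Named character vector of the two table paths, invisibly.
#' @export
write_fixture <- function(traj, dir, basename = traj$group_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_long <- file.path(dir, paste0(basename, "_long.csv"))
  p_wide <- file.path(dir, paste0(basename, "_wide.csv"))
  write_trajectories(traj, p_long, format = "long")
  write_trajectories(traj, p_wide, format = "wide")
  invisible(c(long = p_long, wide = p_wide))
}
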