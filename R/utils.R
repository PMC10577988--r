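# Internal helpers shared across modules.

# Wrap angles to (-pi, pi].
wrap_angle <- function(a) {
  w <- (a + pi) %% (2 * pi) - pi
  w[w == -pi] <- pi
  w
}

# Round half away from zero at the given number of decimals.  Used only for
# presentation (printed nutrient tables round 47.55 up to 47.6, which
# banker's rounding does not).  The 1e-9 guard absorbs binary representation
# error of decimal inputs.
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

# Run `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Index matrix (2 x P) of unordered pairs among n individuals, column order
# (1,2), (1,3), ..., (n-1,n).
pair_index <- function(n) {
  if (n < 2) stop("need at least 2 fish to form pairs", call. = FALSE)
  utils::combn(n, 2)
}

pair_labels <- function(pairs, fish_ids) {
  paste(fish_ids[pairs[1, ]], fish_ids[pairs[2, ]], sep = "-")
}

# Lengths and start indices of TRUE runs in a logical vector (NA = FALSE).
true_runs <- function(q) {
  q[is.na(q)] <- FALSE
  r <- rle(q)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  cbind(start = starts[keep], length = r$lengths[keep])
}
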