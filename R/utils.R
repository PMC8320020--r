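# Internal helpers shared across modules. All internal time is expressed in
# minutes since the recording origin (t = 0 is local midnight of day 0);
# clock time is t %% 1440.

MIN_PER_DAY <- 1440

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp01 <- function(x) pmin(1, pmax(0, x))

#' Wrap angles onto [0, 2*pi)
#' @param theta numeric vector of angles in radians.
#' @return angles wrapped to `[0, 2*pi)`.
#' @keywords internal
wrap_angle <- function(theta) theta %% (2 * pi)

# Circular mean of angles (radians); NA when resultant length is ~0.
circ_mean <- function(theta) {
  s <- sum(sin(theta)); c <- sum(cos(theta))
  if (sqrt(s^2 + c^2) < 1e-12) return(NA_real_)
  atan2(s, c) %% (2 * pi)
}

# Signed circular distance a - b mapped to (-pi, pi].
circ_dist <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

# Phase unwrapping: removes 2*pi jumps so the series is continuous.
unwrap_phase <- function(theta) {
  if (length(theta) < 2) return(theta)
  d <- diff(theta)
  jump <- round(d / (2 * pi))
  theta - c(0, cumsum(jump)) * 2 * pi + theta[1] * 0
}

# Last-observation-carried-forward; leading NAs filled with `first`
# (defaults to the first non-NA value, then 0 if the vector is all-NA).
fill_forward <- function(x, first = NULL) {
  if (!anyNA(x)) return(x)
  ok <- !is.na(x)
  if (!any(ok)) return(rep(first %||% 0, length(x)))
  idx <- cumsum(ok)
  vals <- x[ok]
  out <- ifelse(idx == 0, NA, vals[pmax(idx, 1)])
  out[is.na(out)] <- first %||% vals[1]
  out
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic fan-out of one master seed into k sub-seeds (< 2^31).
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

# next power of two >= n
next_pow2 <- function(n) 2^ceiling(log2(n))
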