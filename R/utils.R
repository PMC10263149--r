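# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic generators route their randomness through this
# so that identical seeds give byte-identical output.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  expr
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (positive && x <= 0) {
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  }
  invisible(x)
}

# First-order autoregressive (discretised Ornstein-Uhlenbeck) series around
# `target` with relaxation rate `rate` (1/s) and stationary SD `sd`.
ou_series <- function(n, dt, target, rate, sd, init = NULL) {
  target <- rep_len(target, n)
  x <- numeric(n)
  x[1] <- if (is.null(init)) target[1] + if (sd > 0) rnorm(1, 0, sd) else 0 else init
  if (n == 1L) return(x)
  a <- exp(-rate * dt)
  innov_sd <- sd * sqrt(1 - a^2)
  eps <- if (sd > 0) rnorm(n - 1L, 0, innov_sd) else numeric(n - 1L)
  for (i in 2:n) {
    x[i] <- target[i] + a * (x[i - 1L] - target[i]) + eps[i - 1L]
  }
  x
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

# Map an axial (180-deg ambiguous) angle into [0, 180).
wrap_axial <- function(deg) {
  out <- deg %% 180
  out[out < 0] <- out[out < 0] + 180
  out
}
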