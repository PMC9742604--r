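#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the previous
#' RNG state afterwards, so library calls never perturb a caller's stream.
#' All stochastic entry points in the package route their randomness through
#' this helper with an explicit seed argument.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic fan-out of one master seed into per-stage sub-seeds,
# kept strictly below 2^31 - 1.
derive_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009 + as.double(k) * 9973) %% 2147483629)
}

# Standardize each row to zero mean, unit (sample) variance over time.
# Rows with zero variance become all-zero with a warning.
standardize_rows <- function(m, warn = TRUE) {
  mu <- rowMeans(m)
  ctr <- m - mu
  s <- sqrt(rowSums(ctr^2) / (ncol(m) - 1))
  zero <- s < .Machine$double.eps * ncol(m)
  if (any(zero)) {
    if (warn) warning(sum(zero), " zero-variance row(s) replaced by zeros")
    s[zero] <- 1
    ctr[zero, ] <- 0
  }
  ctr / s
}

relu <- function(x) pmax(x, 0)
leaky_relu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
sigmoid <- function(x) 1 / (1 + exp(-x))

softmax_rows <- function(x) {
  x <- x - apply(x, 1L, max)
  e <- exp(x)
  e / rowSums(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_shape <- function(...) stop(sprintf(...), call. = FALSE)
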