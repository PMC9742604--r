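# Small shared fixtures and a central finite-difference helper. Everything is
# generated in code with fixed seeds; no binary fixtures.

fb <- asNamespace("fbngan")

num_grad <- function(f, x, eps = 1e-5) {
  g <- array(0, dim = dim(x) %||% length(x))
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rel_err <- function(a, b) {
  max(abs(a - b)) / max(1e-8, max(abs(a)), max(abs(b)))
}

# tiny study used across training/evaluation tests: 4 ROIs in an 8^3 grid,
# 16 frames, strong vs no block correlation
tiny_spec <- function(noise_sd = 0.3) {
  phantom_spec(grid = c(8, 8, 8), n_roi = 4, n_time = 16, radius = 1,
               noise_sd = noise_sd,
               class_cov = list(A = cov_equicorr_block(4, 1:3, 0.8),
                                B = cov_equicorr_block(4, 1:3, 0.0)))
}

tiny_config <- function(spec) fbn_config_for_spec(spec, heads = 4, n_blocks = 2)
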