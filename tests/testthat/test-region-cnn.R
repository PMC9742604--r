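tiny_cnn <- function(seed = 21) {
  cfg <- region_cnn_config(c(8, 8, 8), n_roi = 4, n_time = 6, n_blocks = 2,
                           channels = c(2, 3))
  list(cfg = cfg,
       params = fb$with_seed(seed, fb$region_cnn_init(cfg)),
       stats = fb$region_cnn_stats_init(cfg),
       emb = fb$with_seed(seed + 1, matrix(runif(16), 4, 4)),
       vol = fb$with_seed(seed + 2, array(rnorm(8 * 8 * 8 * 6), c(8, 8, 8, 6))))
}

test_that("output is n_roi x n_time and config validates geometry", {
  s <- tiny_cnn()
  out <- fb$region_cnn_fwd(s$vol, s$emb, s$params, s$stats, s$cfg)
  expect_equal(dim(out$f1), c(4, 6))
  expect_true(all(is.finite(out$f1)))
  # brain-scale geometry contract: 64x64x48 through 4 blocks pools to 4x4x3,
  # so each ROI channel flattens to 48 values (52 with the embedding quad)
  cfg_full <- region_cnn_config(c(64, 64, 48), n_roi = 90, n_time = 187)
  expect_equal(cfg_full$pooled, c(4, 4, 3))
  expect_equal(cfg_full$spatial + 4L, 52L)
  expect_equal(cfg_full$channels, c(8L, 16L, 32L, 64L))
  expect_error(region_cnn_config(c(60, 64, 48), 90, 187), "divisible")
  expect_error(region_cnn_config(c(64, 64, 48), 90, 187,
                                 channels = c(8, 8, 32, 64)), "increasing")
})

test_that("sigmoid stage keeps channel maps in (0, 1); zero weights give bias", {
  s <- tiny_cnn()
  out <- fb$region_cnn_fwd(s$vol, s$emb, s$params, s$stats, s$cfg)
  expect_true(all(out$cache$s > 0 & out$cache$s < 1))

  p0 <- s$params
  for (b in 1:2) p0$blocks[[b]]$conv$w[] <- 0
  p0$head$w[] <- 0
  p0$proj$w[] <- 0
  p0$proj$b <- 0.37
  out0 <- fb$region_cnn_fwd(s$vol, s$emb, p0, s$stats, s$cfg)
  expect_equal(out0$f1, matrix(0.37, 4, 6), ignore_attr = TRUE)
})

test_that("frames are processed independently (column equivariance)", {
  s <- tiny_cnn()
  out <- fb$region_cnn_fwd(s$vol, s$emb, s$params, s$stats, s$cfg)
  perm <- c(3, 1, 6, 2, 4, 5)
  out_p <- fb$region_cnn_fwd(s$vol[, , , perm], s$emb, s$params, s$stats, s$cfg)
  expect_equal(out_p$f1, out$f1[, perm], tolerance = 1e-10)
})

test_that("backward pass delivers finite nonzero gradients everywhere", {
  s <- tiny_cnn()
  fwd <- fb$region_cnn_fwd(s$vol, s$emb, s$params, s$stats, s$cfg)
  lw <- fb$with_seed(5, matrix(rnorm(24), 4, 6))
  bwd <- fb$region_cnn_bwd(lw, fwd$cache, s$params, s$cfg)
  walk <- function(g, path = "") {
    if (is.list(g)) {
      for (nm in names(g) %||% seq_along(g))
        walk(g[[nm]], paste(path, nm))
    } else {
      expect_true(all(is.finite(g)), info = path)
      expect_gt(max(abs(g)), 0)
    }
  }
  walk(bwd)
  # finite-difference check on the first conv kernel
  f_obj <- function(v) {
    p <- s$params
    p$blocks[[1]]$conv$w <- matrix(v, 27, 2)
    sum(fb$region_cnn_fwd(s$vol, s$emb, p, s$stats, s$cfg)$f1 * lw)
  }
  expect_lt(rel_err(num_grad(f_obj, as.vector(s$params$blocks[[1]]$conv$w)),
                    as.vector(bwd$blocks[[1]]$conv$w)), 1e-5)
})

test_that("brain-scale geometry: 90 ROI channels from 64x64x48 volumes", {
  # full 4-block stack at atlas scale, run on 2 frames (frames are
  # processed independently, so the geometry contract is frame-count-free)
  cfg <- region_cnn_config(c(64, 64, 48), n_roi = 90, n_time = 2)
  params <- fb$with_seed(99, fb$region_cnn_init(cfg))
  stats <- fb$region_cnn_stats_init(cfg)
  vol <- fb$with_seed(100, array(rnorm(64 * 64 * 48 * 2), c(64, 64, 48, 2)))
  emb <- fb$with_seed(101, matrix(runif(360), 90, 4))
  out <- fb$region_cnn_fwd(vol, emb, params, stats, cfg)
  expect_equal(dim(out$f1), c(90, 2))
  # sigmoid stage: one 4x4x3 map per ROI channel and frame
  expect_equal(dim(out$cache$s), c(4 * 4 * 3 * 2, 90))
  expect_length(params$proj$w, 52)
  # the attention stage at full scale: 11 heads of width 17 tile q = 187
  sc <- sat_config(90, 187, heads = 11)
  expect_equal(sc$widths, rep(17, 11))
})

test_that("compiled conv/pool primitives match naive R oracles", {
  set.seed(55)
  x <- array(rnorm(4 * 4 * 4 * 2 * 2), c(4, 4, 4, 2, 2))
  w <- matrix(rnorm(54 * 3, sd = 0.3), 54, 3)
  b <- rnorm(3)
  y <- fb$conv3d_fwd(x, w, b)
  conv_naive <- function(x, w, b, i, j, k, co, t) {
    acc <- b[co]
    for (c in 1:2) for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
      ii <- i + dx; jj <- j + dy; kk <- k + dz
      if (ii < 1 || ii > 4 || jj < 1 || jj > 4 || kk < 1 || kk > 4) next
      o <- (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1) + 27 * (c - 1) + 1
      acc <- acc + x[ii, jj, kk, c, t] * w[o, co]
    }
    acc
  }
  for (probe in 1:25) {
    i <- sample(4, 1); j <- sample(4, 1); k <- sample(4, 1)
    co <- sample(3, 1); t <- sample(2, 1)
    expect_equal(y[i, j, k, co, t], conv_naive(x, w, b, i, j, k, co, t),
                 tolerance = 1e-12)
  }
  p <- fb$avgpool3d_fwd(x)
  expect_equal(dim(p), c(2, 2, 2, 2, 2))
  expect_equal(p[1, 2, 1, 2, 1], mean(x[1:2, 3:4, 1:2, 2, 1]), tolerance = 1e-12)
})

test_that("batch normalization tracks running statistics", {
  set.seed(8)
  x <- array(rnorm(4 * 4 * 4 * 2 * 3, mean = 2, sd = 3), c(4, 4, 4, 2, 3))
  pars <- fb$bn_init(2)
  st <- fb$bn_state_init(2)
  out <- fb$bn_fwd(x, pars, st, train = TRUE)
  m <- matrix(aperm(out$y, c(1, 2, 3, 5, 4)), ncol = 2)
  expect_equal(unname(colMeans(m)), c(0, 0), tolerance = 1e-12)
  expect_equal(unname(colMeans(m^2)), c(1, 1), tolerance = 1e-4)
  # running stats move 10% toward the batch (momentum 0.9)
  xm <- matrix(aperm(x, c(1, 2, 3, 5, 4)), ncol = 2)
  expect_equal(out$state$mean, 0.1 * colMeans(xm), tolerance = 1e-12)
  # evaluation mode applies the stored statistics verbatim
  ev <- fb$bn_fwd(x, pars, list(mean = c(2, 2), var = c(9, 9)), train = FALSE)
  em <- matrix(aperm(ev$y, c(1, 2, 3, 5, 4)), ncol = 2)
  expect_equal(unname(colMeans(em)), unname((colMeans(xm) - 2) / sqrt(9 + 1e-5)),
               tolerance = 1e-10)
})
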