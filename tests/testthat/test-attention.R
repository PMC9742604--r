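make_sat <- function(n = 8, q = 32, heads = 4, seed = 9) {
  cfg <- sat_config(n, q, heads)
  list(cfg = cfg, params = fb$with_seed(seed, fb$sat_init(cfg)),
       emb = fb$with_seed(seed + 1, matrix(runif(n * 4), n, 4)),
       f1 = fb$with_seed(seed + 2, matrix(rnorm(n * q), n, q)))
}

test_that("qkv projections have the stated shapes and input dependencies", {
  s <- make_sat()
  qkv <- project_qkv(s$f1, s$emb, s$params)
  expect_equal(dim(qkv$q), c(8, 32))
  expect_equal(dim(qkv$k), c(8, 32))
  expect_equal(dim(qkv$v), c(8, 32))
  expect_equal(dim(s$params$wk), c(36, 32))  # keys consume q + 4 columns

  # zero input and zero bias: all projections vanish
  z <- project_qkv(matrix(0, 8, 32), matrix(0, 8, 4), s$params)
  expect_equal(z$q, matrix(0, 8, 32))
  expect_equal(z$k, matrix(0, 8, 32))

  # embeddings reach keys/values but not queries
  e <- project_qkv(matrix(0, 8, 32), s$emb, s$params)
  expect_equal(e$q, matrix(0, 8, 32))
  expect_gt(max(abs(e$k)), 0)
  expect_gt(max(abs(e$v)), 0)
})

test_that("attention rows are probability vectors; uniform at zero queries", {
  s <- make_sat()
  qkv <- project_qkv(s$f1, s$emb, s$params)
  idx <- s$cfg$slices[[1]]
  ca <- central_attention(qkv$q[, idx], qkv$k[, idx], qkv$v[, idx])
  expect_equal(unname(rowSums(ca$attn)), rep(1, 8), tolerance = 1e-6)

  # zero queries: uniform attention, output row = column mean of V
  vi <- qkv$v[, idx]
  ca0 <- central_attention(matrix(0, 8, 8), qkv$k[, idx], vi)
  expect_equal(ca0$attn, matrix(1 / 8, 8, 8), ignore_attr = TRUE)
  expect_equal(ca0$out[3, ], colMeans(vi), ignore_attr = TRUE)

  # 2-token softmax evaluated by hand: scores (ln 3, 0) -> (0.75, 0.25)
  d <- 4
  qi <- matrix(0, 2, d); ki <- matrix(0, 2, d)
  qi[1, 1] <- log(3) * sqrt(d); ki[1, 1] <- 1
  ca2 <- central_attention(qi, ki, diag(2) %*% matrix(rnorm(2 * d), 2, d))
  expect_equal(unname(ca2$attn[1, ]), c(0.75, 0.25), tolerance = 1e-12)
})

test_that("head splitting covers all columns, remainder to the last head", {
  cfg <- sat_config(5, 32, heads = 4)
  expect_equal(cfg$widths, rep(8, 4))
  cfg_odd <- sat_config(5, 187, heads = 11)
  expect_equal(cfg_odd$widths, c(rep(17, 10), 17))
  cfg_rem <- sat_config(5, 30, heads = 4)
  expect_equal(cfg_rem$widths, c(7, 7, 7, 9))
  expect_equal(sort(unname(unlist(cfg_rem$slices))), 1:30)
  expect_equal(cfg_odd$hidden, 93)  # feed-forward down-map floor(187/2)
})

test_that("attention block collapses to layer-norm of F1 at zero weights", {
  s <- make_sat()
  p0 <- s$params
  p0$wo[] <- 0; p0$bo[] <- 0
  out <- fb$sat_fwd(s$f1, s$emb, p0, s$cfg)
  ln_ref <- fb$ln_fwd(s$f1, p0$ln)$y
  expect_equal(out$smca, ln_ref)
  # layer-norm contract: row mean 0, row variance 1 under unit gain/zero bias
  expect_equal(unname(rowMeans(out$smca)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(out$smca, 1, function(r) mean(r^2))),
               rep(1, 8), tolerance = 1e-3)

  # zero up-map: the feed-forward block is the identity (pure residual)
  p1 <- s$params
  p1$um[] <- 0; p1$umb[] <- 0
  out1 <- fb$sat_fwd(s$f1, s$emb, p1, s$cfg)
  expect_equal(out1$fg, out1$smca)
})

test_that("the refiner is permutation-equivariant over ROIs", {
  s <- make_sat(n = 6, q = 16, heads = 4)
  out <- fb$sat_fwd(s$f1, s$emb, s$params, s$cfg)
  perm <- c(4, 1, 6, 2, 5, 3)
  out_p <- fb$sat_fwd(s$f1[perm, ], s$emb[perm, ], s$params, s$cfg)
  expect_equal(out_p$fg, out$fg[perm, ], tolerance = 1e-12)
})

test_that("gradients reach every attention parameter group", {
  s <- make_sat(n = 4, q = 12, heads = 3)
  lw <- fb$with_seed(12, matrix(rnorm(48), 4, 12))
  fwd <- fb$sat_fwd(s$f1, s$emb, s$params, s$cfg)
  bwd <- fb$sat_bwd(lw, fwd$cache, s$params, s$cfg)
  for (nm in c("wq", "wk", "wv", "wo", "dm", "um")) {
    expect_true(all(is.finite(bwd$grads[[nm]])), info = nm)
    expect_gt(max(abs(bwd$grads[[nm]])), 0)
  }
  expect_gt(max(abs(bwd$grads$ln$gain)), 0)
  # spot finite-difference check through the whole block
  f_obj <- function(v) {
    p <- s$params; p$wq <- matrix(v, 12, 12)
    sum(fb$sat_fwd(s$f1, s$emb, p, s$cfg)$fg * lw)
  }
  expect_lt(rel_err(num_grad(f_obj, as.vector(s$params$wq)),
                    as.vector(bwd$grads$wq)), 1e-6)
})
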