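rand_fc <- function(n, seed) {
  fb$with_seed(seed, {
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    a
  })
}

test_that("adjacency normalization matches a scalar double-loop oracle", {
  set.seed(61)
  for (rep in 1:5) {
    a <- matrix(runif(25), 5, 5); a <- (a + t(a)) / 2; diag(a) <- 1
    ah <- normalize_adjacency(a)
    b <- a + diag(5)
    deg <- rowSums(b)
    for (i in 1:5) for (j in 1:5)
      expect_equal(ah[i, j], b[i, j] / sqrt(deg[i] * deg[j]),
                   tolerance = 1e-12)
    expect_true(isSymmetric(ah))
  }
  # all-zero off-diagonal: isolated nodes self-normalize to the identity
  expect_equal(normalize_adjacency(diag(4)), diag(4), ignore_attr = TRUE)
})

test_that("empirical Pearson input is rescaled to [0, 1] before normalization", {
  r <- rbind(c(1, -1), c(-1, 1))
  ah <- normalize_adjacency(r, empirical = TRUE)
  # off-diagonal -1 -> 0: graph decouples into two self-loops
  expect_equal(ah, diag(2), ignore_attr = TRUE)
  expect_error(normalize_adjacency(matrix(c(1, 0.2, 0.5, 1), 2)), "symmetric")
})

test_that("classifier emits a probability vector over classes", {
  q <- 16
  params <- fb$with_seed(71, fb$gcn_init(5, q, 2))
  f <- fb$with_seed(72, matrix(rnorm(5 * q), 5, q))
  out <- gcn_forward(normalize_adjacency(rand_fc(5, 73)), f, params)
  expect_length(out$probs, 2)
  expect_true(all(out$probs >= 0))
  expect_equal(sum(out$probs), 1, tolerance = 1e-6)
  expect_length(out$pooled, 5)  # pooling: one value per ROI
  # feature widths halve per layer: 16 -> 8 -> 4 -> 2
  expect_equal(vapply(params$gconv, ncol, 0L), c(8L, 4L, 2L))
})

test_that("identity diffusion passes features through unmixed", {
  q <- 8
  params <- fb$with_seed(81, fb$gcn_init(4, q, 2))
  # pad-truncated identity weight matrices, nonnegative input
  params$gconv <- list(rbind(diag(4), matrix(0, 4, 4)),
                       rbind(diag(2), matrix(0, 2, 2)),
                       matrix(c(1, 0), 2, 1))
  f <- abs(fb$with_seed(82, matrix(rnorm(32), 4, 8)))
  out <- gcn_forward(diag(4), f, params)
  expect_equal(out$pooled, unname(f[, 1]))
})

test_that("classification is invariant to graph isomorphism", {
  q <- 12
  params <- fb$with_seed(91, fb$gcn_init(6, q, 2))
  a <- rand_fc(6, 92)
  f <- fb$with_seed(93, matrix(rnorm(6 * q), 6, q))
  out <- gcn_forward(normalize_adjacency(a), f, params)
  perm <- c(5, 3, 6, 1, 2, 4)
  # permute graph and features; permute the pooling->perceptron weights to match
  params_p <- params
  params_p$mlp$l1$w <- params$mlp$l1$w[perm, , drop = FALSE]
  out_p <- gcn_forward(normalize_adjacency(a[perm, perm]), f[perm, ], params_p)
  expect_equal(out_p$probs, out$probs, tolerance = 1e-12)
  expect_equal(out_p$pooled, out$pooled[perm], tolerance = 1e-12)
})

test_that("normalization and classifier backward passes verify numerically", {
  a <- rand_fc(5, 95)
  dah <- fb$with_seed(96, { m <- matrix(rnorm(25), 5); (m + t(m)) / 2 })
  bwd <- fb$normalize_adjacency_bwd(dah, a)
  norm_free <- function(m) {
    b <- m + diag(5); s <- 1 / sqrt(rowSums(b)); b * outer(s, s)
  }
  expect_lt(rel_err(num_grad(function(v)
    sum(norm_free(matrix(v, 5, 5)) * dah), as.vector(a)),
    as.vector(bwd)), 1e-6)

  params <- fb$with_seed(97, fb$gcn_init(5, 16, 2))
  f <- fb$with_seed(98, matrix(rnorm(80), 5, 16))
  ah <- normalize_adjacency(a)
  out <- gcn_forward(ah, f, params)
  y <- c(0, 1)
  gb <- fb$gcn_bwd(out$probs - y, out$cache, params)
  ce <- function(p) sum(-y * log(pmax(p, 1e-12)))
  f_w <- function(v) {
    p <- params; p$gconv[[2]] <- matrix(v, 8, 4)
    ce(gcn_forward(ah, f, p)$probs)
  }
  expect_lt(rel_err(num_grad(f_w, as.vector(params$gconv[[2]])),
                    as.vector(gb$grads$gconv[[2]])), 1e-5)
  f_a <- function(v) ce(gcn_forward(matrix(v, 5, 5), f, params)$probs)
  expect_lt(rel_err(num_grad(f_a, as.vector(ah)), as.vector(gb$dahat)), 1e-5)
})
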