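test_that("embedding normalization min-max scales each descriptor", {
  atlas <- make_atlas(3, grid = c(32, 16, 16), radius = 2)
  atlas$cx <- c(10, 20, 30)
  emb <- normalize_embeddings(atlas)
  expect_equal(unname(emb[, "ex"]), c(0, 0.5, 1))
  # equal volumes (same radius everywhere) hit the constant-descriptor rule
  expect_equal(unname(emb[, "ev"]), rep(0.5, 3))

  # hand computation of (x - min) / (max - min) on four centers
  atlas4 <- make_atlas(4, grid = c(48, 16, 16), radius = 2)
  atlas4$cx <- c(3, 7, 5, 9)
  emb4 <- normalize_embeddings(atlas4)
  expect_equal(unname(emb4[, "ex"]), c(0, 2 / 3, 1 / 3, 1))

  expect_error(normalize_embeddings(make_atlas(2)[1, , drop = FALSE]),
               "at least 2")
})

test_that("atlas geometry is valid: disjoint in-bounds spheres", {
  for (n in c(4, 8, 27)) {
    atlas <- make_atlas(n, grid = c(24, 24, 24), radius = 2)
    vox <- roi_voxel_sets(atlas)
    expect_equal(anyDuplicated(unlist(vox)), 0L)
    expect_equal(lengths(vox), atlas$volume)
    expect_true(all(atlas$volume >= 1))
  }
  expect_error(make_atlas(100, grid = c(8, 8, 8), radius = 2), "too small")
})

test_that("phantom simulation is seeded and respects the zero-noise limit", {
  spec <- phantom_spec(grid = c(8, 8, 8), n_roi = 4, n_time = 12, radius = 1,
                       noise_sd = 0,
                       class_cov = list(A = cov_equicorr_block(4, 1:2, 0.5)))
  ph1 <- simulate_phantom(spec, "A", seed = 11)
  ph2 <- simulate_phantom(spec, "A", seed = 11)
  expect_identical(ph1$volume, ph2$volume)
  ph3 <- simulate_phantom(spec, "A", seed = 12)
  expect_false(identical(ph1$volume, ph3$volume))

  # noise sd = 0: every in-ROI voxel carries exactly its ROI's series
  vox <- roi_voxel_sets(spec$atlas)
  vm <- matrix(ph1$volume, prod(spec$grid), spec$n_time)
  for (i in 1:4)
    for (v in vox[[i]])
      expect_equal(unname(vm[v, ]), unname(ph1$truth[i, ]))
  # out-of-ROI voxels are pure (zero) noise
  outside <- setdiff(seq_len(prod(spec$grid)), unlist(vox))
  expect_true(all(vm[outside, ] == 0))

  # extraction recovers the standardized truth
  fe <- extract_empirical_series(ph1$volume, spec$atlas)
  truth_std <- t(apply(ph1$truth, 1, function(r) (r - mean(r)) / sd(r)))
  expect_lt(max(abs(fe - truth_std)), 1e-9)
})

test_that("phantom spec validation rejects bad covariances", {
  bad <- matrix(c(1, 2, 2, 1), 2)  # indefinite
  expect_error(phantom_spec(n_roi = 2, class_cov = list(A = bad)),
               "positive semidefinite")
  asym <- matrix(c(1, 0.5, 0.1, 1), 2)
  expect_error(phantom_spec(n_roi = 2, class_cov = list(A = asym)),
               "symmetric")
})

test_that("planted block correlations show up in the sampled series", {
  # Monte-Carlo check of the sampling distribution of r at n = 200:
  # two 4-ROI communities with block correlation 0.8
  S <- cov_equicorr_block(8, 1:4, 0.8)
  S[5:8, 5:8] <- 0.8; diag(S) <- 1
  spec <- phantom_spec(grid = c(24, 24, 24), n_roi = 8, n_time = 200,
                       radius = 2, noise_sd = 0,
                       class_cov = list(A = S))
  hits <- 0; total <- 0
  for (seed in 1:5) {
    ph <- simulate_phantom(spec, "A", seed)
    r <- pearson_fc(ph$truth)
    for (blk in list(1:4, 5:8)) {
      pairs <- t(combn(blk, 2))
      vals <- r[pairs]
      hits <- hits + sum(vals >= 0.7 & vals <= 0.9)
      total <- total + length(vals)
    }
  }
  expect_gte(hits / total, 0.9)
})

test_that("empirical series extraction averages voxels and standardizes", {
  # 2-voxel ROI with frame means 1, 3 -> pre-standardization mean 2
  spec <- phantom_spec(grid = c(8, 8, 8), n_roi = 2, n_time = 3, radius = 1,
                       noise_sd = 0, class_cov = list(A = diag(2)))
  vol <- array(0, c(8, 8, 8, 3))
  vox <- roi_voxel_sets(spec$atlas)
  vm <- matrix(vol, 512, 3)
  vm[vox[[1]], ] <- rep(c(1, 2, 3), each = length(vox[[1]]))
  vm[vox[[1]][1], ] <- c(0, 2, 4)   # mixed voxels, same mean per frame
  vm[vox[[1]][2], ] <- c(2, 2, 2)
  vm[vox[[2]], ] <- 5               # constant ROI -> zero row + warning
  dim(vm) <- c(8, 8, 8, 3)
  expect_warning(fe <- extract_empirical_series(vm, spec$atlas),
                 "zero-variance")
  expect_equal(unname(fe[2, ]), c(0, 0, 0))
  expect_equal(mean(fe[1, ]), 0)
  expect_equal(sd(fe[1, ]), 1)
})

test_that("pearson_fc matches the textbook formula and conventions", {
  expect_equal(pearson_fc(rbind(c(1, 2, 3), c(3, 2, 1)))[1, 2], -1)
  expect_equal(pearson_fc(rbind(c(1, 2, 3), c(1, 3, 2)))[1, 2], 0.5)

  # independent scalar-loop oracle on random matrices
  scalar_cor <- function(x, y) {
    mx <- mean(x); my <- mean(y)
    sum((x - mx) * (y - my)) /
      sqrt(sum((x - mx)^2) * sum((y - my)^2))
  }
  set.seed(31)
  for (rep in 1:3) {
    m <- matrix(rnorm(8 * 32), 8, 32)
    r <- pearson_fc(m)
    expect_true(isSymmetric(r))
    expect_equal(unname(diag(r)), rep(1, 8))
    for (i in 1:7) for (j in (i + 1):8)
      expect_equal(r[i, j], scalar_cor(m[i, ], m[j, ]), tolerance = 1e-12)
  }
  # zero-variance rows correlate as zero, not NaN
  m <- rbind(rep(1, 8), rnorm(8))
  r <- pearson_fc(m)
  expect_equal(r[1, 2], 0)
  expect_equal(diag(r), c(1, 1))
  expect_error(pearson_fc(matrix(1:4, 2)), "3 time points")
})

test_that("study simulation is reproducible and balanced", {
  spec <- tiny_spec()
  s1 <- simulate_study(spec, n_per_class = 3, seed = 5)
  s2 <- simulate_study(spec, n_per_class = 3, seed = 5)
  expect_identical(s1$subjects[[2]]$volume, s2$subjects[[2]]$volume)
  expect_equal(table(vapply(s1$subjects, `[[`, "", "class")),
               table(rep(c("A", "B"), each = 3)), ignore_attr = TRUE)
  expect_equal(dim(s1$subjects[[1]]$series_emp), c(4, 16))
  expect_equal(dim(s1$subjects[[1]]$fc_emp), c(4, 4))
})
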