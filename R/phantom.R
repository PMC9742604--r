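#' Specify a synthetic fMRI phantom
#'
#' A phantom draws, per subject, a zero-mean multivariate-normal ROI signal
#' (independently across time points) from a class-specific covariance, paints
#' each ROI's signal onto the voxels of its sphere, and adds independent
#' Gaussian voxel noise; out-of-ROI voxels carry pure noise. Class-dependent
#' covariance structure plants known connectivity differences between
#' diagnostic groups, so downstream recovery can be verified.
#'
#' The default covariances realize two groups that differ on the six edges of
#' a four-ROI community: pairwise latent correlation 0.8 in class `"A"` versus
#' 0.1 in class `"B"`.
#'
#' @param grid length-3 grid dimensions.
#' @param n_roi number of ROIs.
#' @param n_time number of time points (frames) per subject.
#' @param radius ROI sphere radius in voxels.
#' @param noise_sd standard deviation of the additive voxel noise (the latent
#'   ROI signals have unit variance).
#' @param class_cov named list of `n_roi` x `n_roi` positive-semidefinite
#'   covariance matrices, one per diagnostic class.
#' @return an object of class `phantom_spec`.
#' @seealso [cov_equicorr_block()], [cov_hub()], [simulate_phantom()]
#' @export
phantom_spec <- function(grid = c(16L, 16L, 16L), n_roi = 8L, n_time = 64L,
                         radius = 2, noise_sd = 0.5,
                         class_cov = list(
                           A = cov_equicorr_block(n_roi, 1:4, 0.8),
                           B = cov_equicorr_block(n_roi, 1:4, 0.1))) {
  if (noise_sd < 0) stop("noise_sd must be nonnegative", call. = FALSE)
  if (n_time < 3) stop("need at least 3 time points", call. = FALSE)
  if (is.null(names(class_cov)) || any(names(class_cov) == ""))
    stop("class_cov must be a named list", call. = FALSE)
  for (cl in names(class_cov)) {
    S <- class_cov[[cl]]
    if (!is.matrix(S) || nrow(S) != n_roi || ncol(S) != n_roi)
      stop("covariance for class ", cl, " must be ", n_roi, "x", n_roi, call. = FALSE)
    if (max(abs(S - t(S))) > 1e-9)
      stop("covariance for class ", cl, " is not symmetric", call. = FALSE)
    ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev)))
      stop("covariance for class ", cl, " is not positive semidefinite", call. = FALSE)
  }
  atlas <- make_atlas(n_roi, grid = grid, radius = radius)
  structure(list(grid = as.integer(grid), n_roi = as.integer(n_roi),
                 n_time = as.integer(n_time), radius = radius,
                 noise_sd = noise_sd, class_cov = class_cov,
                 classes = names(class_cov), atlas = atlas),
            class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("fMRI phantom spec:", paste(x$grid, collapse = "x"), "grid,",
      x$n_roi, "ROIs (radius", paste(unique(x$radius), collapse = "/"),
      "),", x$n_time, "frames\n")
  cat("  classes:", paste(x$classes, collapse = ", "),
      " voxel noise sd:", x$noise_sd, "\n")
  cat("  planted class-difference edges:",
      nrow(planted_edges(x)), "\n")
  invisible(x)
}

#' Equicorrelated-block covariance
#'
#' Unit-variance covariance in which the ROIs in `members` share pairwise
#' correlation `r` and all other ROIs are independent.
#'
#' @param n_roi total number of ROIs.
#' @param members indices of the correlated community.
#' @param r pairwise correlation inside the community.
#' @return an `n_roi` x `n_roi` covariance matrix.
#' @export
cov_equicorr_block <- function(n_roi, members, r) {
  S <- diag(n_roi)
  S[members, members] <- r
  diag(S) <- 1
  S
}

#' Hub covariance: one ROI correlated with a target set
#'
#' Correlation `r_hub` between the hub and each target and `r_tt` among the
#' targets. With `r_tt = r_hub^2` this is the factor model
#' `x_j = r * z + sqrt(1 - r^2) * e_j` with the hub carrying `z`. Keeping
#' `r_tt` fixed across classes while `r_hub` changes confines the class
#' signal to edges incident on the hub, so that ROI is the unique carrier of
#' the group difference — the configuration ROI-shielding analyses should
#' recover.
#'
#' @param n_roi total number of ROIs.
#' @param hub index of the hub ROI.
#' @param targets indices correlated with the hub.
#' @param r_hub hub-target correlation.
#' @param r_tt target-target correlation (default `r_hub^2`).
#' @return an `n_roi` x `n_roi` covariance matrix.
#' @export
cov_hub <- function(n_roi, hub, targets, r_hub, r_tt = r_hub^2) {
  if (hub %in% targets) stop("hub cannot be one of its targets", call. = FALSE)
  S <- diag(n_roi)
  S[hub, targets] <- S[targets, hub] <- r_hub
  S[targets, targets] <- r_tt
  diag(S) <- 1
  S
}

#' Phantom spec with the class signal confined to one hub ROI
#'
#' Both classes share the same target-target correlation structure; only the
#' hub-target edges differ (`r_hub` in class `"A"`, absent in class `"B"`),
#' so the hub is the unique carrier of the diagnostic signal.
#'
#' @inheritParams phantom_spec
#' @param hub hub ROI index.
#' @param targets target ROI indices.
#' @param r_hub hub-target correlation in class `"A"`.
#' @return a [phantom_spec()].
#' @export
phantom_spec_hub <- function(grid = c(16L, 16L, 16L), n_roi = 8L,
                             n_time = 64L, radius = 2, noise_sd = 0.5,
                             hub = 3L, targets = 5:8, r_hub = 0.8) {
  phantom_spec(grid = grid, n_roi = n_roi, n_time = n_time, radius = radius,
               noise_sd = noise_sd,
               class_cov = list(
                 A = cov_hub(n_roi, hub, targets, r_hub),
                 B = cov_hub(n_roi, hub, targets, 0, r_tt = r_hub^2)))
}

#' Edges on which the class covariances differ
#'
#' @param spec a [phantom_spec()].
#' @param tol absolute tolerance for calling two covariance entries different.
#' @return a two-column matrix (`i`, `j`) of upper-triangle ROI pairs.
#' @export
planted_edges <- function(spec, tol = 1e-12) {
  stopifnot(inherits(spec, "phantom_spec"))
  ref <- spec$class_cov[[1]]
  dif <- matrix(FALSE, spec$n_roi, spec$n_roi)
  for (S in spec$class_cov[-1]) dif <- dif | abs(S - ref) > tol
  idx <- which(dif & upper.tri(dif), arr.ind = TRUE)
  colnames(idx) <- c("i", "j")
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

#' Simulate one phantom subject
#'
#' @param spec a [phantom_spec()].
#' @param class_label one of `spec$classes`.
#' @param seed integer seed; identical `(spec, class_label, seed)` give
#'   bit-identical output.
#' @return list with `volume` (4D array X,Y,Z,T), `atlas`, and `truth`
#'   (the `n_roi` x `n_time` latent ROI series).
#' @export
simulate_phantom <- function(spec, class_label, seed) {
  stopifnot(inherits(spec, "phantom_spec"))
  if (!class_label %in% spec$classes)
    stop("unknown class: ", class_label, call. = FALSE)
  S <- spec$class_cov[[class_label]]
  N <- spec$n_roi; q <- spec$n_time
  vox <- roi_voxel_sets(spec$atlas, spec$grid)
  V <- prod(spec$grid)
  with_seed(seed, {
    L <- t(chol(S + diag(1e-10, N)))
    truth <- L %*% matrix(rnorm(N * q), N, q)
    vol <- if (spec$noise_sd > 0)
      matrix(rnorm(V * q, sd = spec$noise_sd), V, q)
    else matrix(0, V, q)
    for (i in seq_len(N))
      vol[vox[[i]], ] <- vol[vox[[i]], , drop = FALSE] +
        rep(truth[i, ], each = length(vox[[i]]))
    dim(vol) <- c(spec$grid, q)
    list(volume = vol, atlas = spec$atlas, truth = truth)
  })
}

#' Simulate a multi-subject phantom study
#'
#' Balanced cohort across the spec's classes; each subject gets a derived seed
#' so the whole study is reproducible from one master seed. Empirical ROI
#' series (`F_e`, ROI-mean extraction + per-row standardization) and empirical
#' Pearson connectivity (`A_e`) are computed for every subject.
#'
#' @param spec a [phantom_spec()].
#' @param n_per_class subjects per class.
#' @param seed master seed.
#' @param keep_volumes keep the 4D arrays in memory (needed for training).
#' @return an object of class `phantom_study`: list with `spec`, `atlas`,
#'   `emb` (normalized ROI embeddings) and `subjects`, each subject a list
#'   `(id, class, volume, series_emp, fc_emp, truth)`.
#' @export
simulate_study <- function(spec, n_per_class = 10L, seed = 1L,
                           keep_volumes = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  subjects <- list()
  k <- 0L
  for (cl in spec$classes) {
    for (s in seq_len(n_per_class)) {
      k <- k + 1L
      ph <- simulate_phantom(spec, cl, derive_seed(seed, k))
      fe <- extract_empirical_series(ph$volume, spec$atlas)
      subjects[[k]] <- list(
        id = sprintf("sub-%03d", k), class = cl,
        volume = if (keep_volumes) ph$volume else NULL,
        series_emp = fe, fc_emp = pearson_fc(fe),
        truth = ph$truth)
    }
  }
  structure(list(spec = spec, atlas = spec$atlas,
                 emb = normalize_embeddings(spec$atlas),
                 subjects = subjects),
            class = "phantom_study")
}

#' @export
print.phantom_study <- function(x, ...) {
  cl <- vapply(x$subjects, `[[`, "", "class")
  cat("phantom study:", length(x$subjects), "subjects (",
      paste(sprintf("%s=%d", names(table(cl)), table(cl)), collapse = ", "),
      "),", x$spec$n_roi, "ROIs x", x$spec$n_time, "frames\n")
  invisible(x)
}

#' Extract empirical ROI time series from a 4D volume
#'
#' Row `i` at frame `t` is the mean intensity over ROI `i`'s voxels; each row
#' is then standardized to zero mean and unit variance over time. This is the
#' package's stand-in for toolbox-derived "empirical" ROI series. Rows with
#' zero variance are flagged with a warning and replaced by zeros.
#'
#' @param volume 4D array (X, Y, Z, T).
#' @param atlas an atlas `data.frame`.
#' @return an `n_roi` x `n_time` matrix with ROI names as rownames.
#' @export
extract_empirical_series <- function(volume, atlas) {
  d <- dim(volume)
  if (length(d) != 4) stop_shape("volume must be a 4D array")
  vox <- roi_voxel_sets(atlas, d[1:3])
  if (any(lengths(vox) == 0))
    stop("ROI with empty voxel set: atlas does not fit this grid", call. = FALSE)
  vm <- matrix(volume, prod(d[1:3]), d[4])
  raw <- t(vapply(vox, function(v) colMeans(vm[v, , drop = FALSE]),
                  numeric(d[4])))
  out <- standardize_rows(raw)
  rownames(out) <- atlas$name
  out
}

#' Pearson functional connectivity between ROI time series
#'
#' @param series an `n_roi` x `n_time` matrix (rows are ROI series).
#' @return symmetric `n_roi` x `n_roi` correlation matrix with unit diagonal.
#'   Zero-variance rows correlate as 0 by convention so downstream matrices
#'   stay finite.
#' @examples
#' pearson_fc(rbind(c(1, 2, 3), c(3, 2, 1)))
#' @export
pearson_fc <- function(series) {
  if (ncol(series) < 3) stop("need at least 3 time points", call. = FALSE)
  z <- standardize_rows(series, warn = FALSE)
  r <- tcrossprod(z) / (ncol(series) - 1)
  r[r > 1] <- 1; r[r < -1] <- -1
  r[upper.tri(r)] <- t(r)[upper.tri(r)]
  diag(r) <- 1
  dimnames(r) <- list(rownames(series), rownames(series))
  r
}
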