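#' Build a synthetic spherical parcellation atlas
#'
#' Places `n_roi` non-overlapping spherical ROIs on a regular lattice inside a
#' 3D voxel grid, emulating an AAL-style parcellation at phantom scale. Centers
#' are 0-based voxel coordinates; `volume` is the voxel count of each sphere.
#'
#' @param n_roi number of ROIs (at least 2).
#' @param grid integer length-3 vector of grid dimensions (X, Y, Z).
#' @param radius sphere radius in voxels; scalar or length-`n_roi` vector.
#' @return a `data.frame` with columns `index`, `name`, `cx`, `cy`, `cz`,
#'   `volume`, carrying `grid` and `radius` attributes.
#' @examples
#' atlas <- make_atlas(8, grid = c(16, 16, 16), radius = 2)
#' @export
make_atlas <- function(n_roi, grid = c(16L, 16L, 16L), radius = 2) {
  if (n_roi < 2) stop("an atlas needs at least 2 ROIs", call. = FALSE)
  grid <- as.integer(grid)
  radius <- rep_len(radius, n_roi)
  rmax <- max(radius)
  spacing <- 2L * as.integer(ceiling(rmax)) + 1L
  slots <- pmax(0L, (grid - 2L * as.integer(ceiling(rmax)) - 1L) %/% spacing) + 1L
  if (prod(slots) < n_roi)
    stop(sprintf("grid %s too small for %d ROIs of radius %g",
                 paste(grid, collapse = "x"), n_roi, rmax), call. = FALSE)
  pos <- expand.grid(x = seq_len(slots[1]) - 1L,
                     y = seq_len(slots[2]) - 1L,
                     z = seq_len(slots[3]) - 1L)
  pos <- pos[seq_len(n_roi), , drop = FALSE]
  ctr <- as.matrix(pos) * spacing + as.integer(ceiling(rmax))
  atlas <- data.frame(
    index = seq_len(n_roi),
    name = sprintf("R%03d", seq_len(n_roi)),
    cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3],
    volume = NA_integer_,
    stringsAsFactors = FALSE
  )
  attr(atlas, "grid") <- grid
  attr(atlas, "radius") <- radius
  vox <- roi_voxel_sets(atlas, grid)
  atlas$volume <- lengths(vox)
  validate_atlas(atlas, grid)
  atlas
}

#' Voxel membership of each ROI
#'
#' @param atlas an atlas `data.frame` (see [make_atlas()]).
#' @param grid grid dimensions; defaults to the atlas `grid` attribute.
#' @return list of integer vectors of 1-based linear voxel indices into an
#'   `X*Y*Z` array, one per ROI.
#' @export
roi_voxel_sets <- function(atlas, grid = attr(atlas, "grid")) {
  if (is.null(grid)) stop("grid dimensions required", call. = FALSE)
  radius <- attr(atlas, "radius") %||% rep(2, nrow(atlas))
  radius <- rep_len(radius, nrow(atlas))
  lapply(seq_len(nrow(atlas)), function(i) {
    r <- radius[i]
    ri <- as.integer(floor(r))
    cx <- atlas$cx[i]; cy <- atlas$cy[i]; cz <- atlas$cz[i]
    xs <- max(0L, cx - ri):min(grid[1] - 1L, cx + ri)
    ys <- max(0L, cy - ri):min(grid[2] - 1L, cy + ri)
    zs <- max(0L, cz - ri):min(grid[3] - 1L, cz + ri)
    g <- expand.grid(x = xs, y = ys, z = zs)
    keep <- (g$x - cx)^2 + (g$y - cy)^2 + (g$z - cz)^2 <= r^2
    g <- g[keep, , drop = FALSE]
    sort(1L + g$x + grid[1] * (g$y + grid[2] * g$z))
  })
}

validate_atlas <- function(atlas, grid = attr(atlas, "grid")) {
  need <- c("index", "name", "cx", "cy", "cz", "volume")
  if (!all(need %in% names(atlas)))
    stop("atlas must have columns ", paste(need, collapse = ", "), call. = FALSE)
  if (nrow(atlas) < 2) stop("an atlas needs at least 2 ROIs", call. = FALSE)
  if (!identical(as.integer(atlas$index), seq_len(nrow(atlas))))
    stop("ROI indices must be 1..N, unique and contiguous", call. = FALSE)
  if (any(atlas$volume < 1)) stop("every ROI must contain at least 1 voxel", call. = FALSE)
  if (!is.null(grid)) {
    inb <- atlas$cx >= 0 & atlas$cx < grid[1] &
           atlas$cy >= 0 & atlas$cy < grid[2] &
           atlas$cz >= 0 & atlas$cz < grid[3]
    if (!all(inb)) stop("ROI centers must lie inside the grid", call. = FALSE)
    vox <- roi_voxel_sets(atlas, grid)
    all_vox <- unlist(vox)
    if (anyDuplicated(all_vox))
      stop("ROI voxel sets overlap", call. = FALSE)
  }
  invisible(atlas)
}

#' Min-max normalize ROI centers and volumes into the unit interval
#'
#' Each of the four geometric descriptors (center x, y, z and volume) is
#' min-max scaled across ROIs into the unit interval; a descriptor that is
#' constant across all ROIs maps to 0.5 everywhere. The resulting quadruples
#' condition the generator on where each ROI sits and how large it is.
#'
#' @param atlas an atlas `data.frame`.
#' @return an `n_roi` x 4 numeric matrix with columns `ex`, `ey`, `ez`, `ev`.
#' @examples
#' emb <- normalize_embeddings(make_atlas(8))
#' stopifnot(all(emb >= 0 & emb <= 1))
#' @export
normalize_embeddings <- function(atlas) {
  if (nrow(atlas) < 2) stop("an atlas needs at least 2 ROIs", call. = FALSE)
  raw <- cbind(ex = atlas$cx, ey = atlas$cy, ez = atlas$cz, ev = atlas$volume)
  apply(raw, 2L, function(col) {
    rng <- range(col)
    if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2])))
      rep(0.5, length(col))
    else (col - rng[1]) / diff(rng)
  })
}
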