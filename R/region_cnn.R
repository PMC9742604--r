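#' Configure the region-guided 3D convolutional feature network
#'
#' The front end of the generator: per fMRI frame, a stack of blocks
#' (3x3x3 convolution, stride 1, "same" padding; 2x2x2 average pooling,
#' stride 2; batch normalization; ReLU), then a 1x1x1 convolution expanding
#' to one channel per ROI followed by a sigmoid. For ROI `i`, the `i`-th
#' channel's pooled spatial map is flattened, concatenated with that ROI's
#' normalized `(x, y, z, v)` embedding, and reduced to one scalar by a single
#' linear projection shared across ROIs and frames. Stacking scalars over
#' ROIs and frames yields the rough `n_roi` x `n_time` feature matrix.
#'
#' @param grid length-3 spatial grid dimensions; each must be divisible by
#'   `2^n_blocks`.
#' @param n_roi number of ROIs.
#' @param n_time number of frames.
#' @param n_blocks number of conv/pool/BN/ReLU blocks (4 at full brain scale,
#'   fewer for small phantoms).
#' @param channels output channels per block, positive and increasing;
#'   defaults to the first `n_blocks` of (8, 16, 32, 64).
#' @return a `region_cnn_config` list.
#' @export
region_cnn_config <- function(grid, n_roi, n_time, n_blocks = 4L,
                              channels = c(8L, 16L, 32L, 64L)[seq_len(n_blocks)]) {
  grid <- as.integer(grid)
  n_blocks <- as.integer(n_blocks)
  if (length(channels) != n_blocks)
    stop("need one channel count per block", call. = FALSE)
  if (any(channels <= 0) || any(diff(channels) <= 0))
    stop("channel counts must be positive and increasing", call. = FALSE)
  if (any(grid %% 2L^n_blocks != 0L))
    stop_shape("grid dims (%s) must be divisible by 2^%d",
               paste(grid, collapse = "x"), n_blocks)
  pooled <- grid %/% 2L^n_blocks
  list(grid = grid, n_roi = as.integer(n_roi), n_time = as.integer(n_time),
       n_blocks = n_blocks, channels = as.integer(channels),
       pooled = pooled, spatial = prod(pooled))
}

region_cnn_init <- function(config) {
  blocks <- list()
  cin <- 1L
  for (b in seq_len(config$n_blocks)) {
    cout <- config$channels[b]
    blocks[[b]] <- list(
      conv = list(w = matrix(rnorm(27 * cin * cout, sd = sqrt(2 / (27 * cin))),
                             27 * cin, cout),
                  b = rep(0, cout)),
      bn = bn_init(cout))
    cin <- cout
  }
  head_w <- matrix(rnorm(cin * config$n_roi, sd = sqrt(2 / cin)),
                   cin, config$n_roi)
  pin <- config$spatial + 4L
  list(blocks = blocks,
       head = list(w = head_w, b = rep(0, config$n_roi)),
       proj = list(w = rnorm(pin, sd = sqrt(1 / pin)), b = 0))
}

region_cnn_stats_init <- function(config) {
  lapply(config$channels, bn_state_init)
}

# volume: (X,Y,Z,T); emb: n_roi x 4. Returns F1 (n_roi x n_time), a cache for
# the backward pass, and updated batch-norm running statistics.
region_cnn_fwd <- function(volume, emb, params, stats, config, train = TRUE) {
  d <- dim(volume)
  if (!identical(as.integer(d[1:3]), config$grid) || d[4] != config$n_time)
    stop_shape("volume is %s, config expects %sx%d",
               paste(d, collapse = "x"),
               paste(config$grid, collapse = "x"), config$n_time)
  if (nrow(emb) != config$n_roi) stop_shape("embeddings must have n_roi rows")
  x <- volume
  dim(x) <- c(d[1:3], 1L, d[4])
  caches <- vector("list", config$n_blocks)
  for (b in seq_len(config$n_blocks)) {
    blk <- params$blocks[[b]]
    y <- conv3d_fwd(x, blk$conv$w, blk$conv$b)
    p <- avgpool3d_fwd(y)
    bn <- bn_fwd(p, blk$bn, stats[[b]], train = train)
    stats[[b]] <- bn$state
    a <- pmax(bn$y, 0)
    caches[[b]] <- list(x = x, pool_in_dims = dim(y), bn_cache = bn$cache,
                        mask = bn$y > 0)
    x <- a
  }
  ds <- dim(x)                       # (Xs, Ys, Zs, C_last, T)
  Vs <- prod(ds[1:3]); Tn <- ds[5]
  m <- matrix(aperm(x, c(1, 2, 3, 5, 4)), Vs * Tn, ds[4])
  z1 <- sweep(m %*% params$head$w, 2L, params$head$b, `+`)
  s <- sigmoid(z1)                   # (Vs*T) x n_roi
  w1 <- params$proj$w[seq_len(Vs)]
  w2 <- params$proj$w[Vs + 1:4]
  conv_part <- t(matrix(crossprod(matrix(s, Vs), w1), Tn, config$n_roi))
  f1 <- conv_part + drop(emb %*% w2) + params$proj$b
  list(f1 = f1,
       cache = list(caches = caches, m = m, s = s, ds = ds, emb = emb),
       stats = stats)
}

region_cnn_bwd <- function(df1, cache, params, config) {
  ds <- cache$ds
  Vs <- prod(ds[1:3]); Tn <- ds[5]
  s <- cache$s
  w1 <- params$proj$w[seq_len(Vs)]
  dvec <- as.vector(t(df1))                       # (t fastest, then ROI)
  dw1 <- drop(matrix(s, Vs) %*% dvec)
  dw2 <- drop(crossprod(cache$emb, rowSums(df1)))
  dproj_b <- sum(df1)
  dsm <- outer(w1, dvec)                          # Vs x (T * n_roi)
  dim(dsm) <- c(Vs * Tn, config$n_roi)
  dz1 <- dsm * s * (1 - s)
  dhead_w <- crossprod(cache$m, dz1)
  dhead_b <- colSums(dz1)
  dm <- dz1 %*% t(params$head$w)
  dim(dm) <- c(ds[1:3], ds[5], ds[4])
  dx <- aperm(dm, c(1, 2, 3, 5, 4))
  dblocks <- vector("list", config$n_blocks)
  for (b in rev(seq_len(config$n_blocks))) {
    ch <- cache$caches[[b]]
    da <- dx * ch$mask
    bnb <- bn_bwd(da, ch$bn_cache, params$blocks[[b]]$bn)
    dp <- avgpool3d_bwd(bnb$dx, ch$pool_in_dims)
    cvb <- conv3d_bwd(ch$x, params$blocks[[b]]$conv$w, dp)
    dblocks[[b]] <- list(conv = list(w = cvb$dw, b = cvb$db),
                         bn = list(gamma = bnb$dgamma, beta = bnb$dbeta))
    dx <- cvb$dx
  }
  list(blocks = dblocks,
       head = list(w = dhead_w, b = dhead_b),
       proj = list(w = c(dw1, dw2), b = dproj_b))
}
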