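#' Configure the spatial-temporal attention refiner
#'
#' Refines the rough per-ROI features into generated ROI time series. Each
#' ROI is a token of width `n_time`. Queries come from the rough features
#' alone; keys and values additionally see the four normalized atlas
#' descriptors (center x, y, z and volume) appended to each token. Multi-head
#' scaled dot-product attention mixes tokens across ROIs, a shared output
#' projection with a residual connection and row-wise layer normalization
#' (post-norm) forms the spatial block, and a temporal feed-forward block
#' (down-map to `floor(n_time/2)` with ReLU, up-map back, residual) produces
#' the generated series.
#'
#' When `heads` does not divide `n_time`, every head gets
#' `floor(n_time/heads)` columns and the last head absorbs the remainder.
#'
#' @param n_roi number of ROI tokens.
#' @param n_time token width (time points).
#' @param heads number of attention heads (11 at full brain scale).
#' @return a `sat_config` list.
#' @export
sat_config <- function(n_roi, n_time, heads = 11L) {
  heads <- as.integer(heads)
  if (heads < 1 || heads > n_time)
    stop("heads must be between 1 and n_time", call. = FALSE)
  base <- n_time %/% heads
  widths <- rep(base, heads)
  widths[heads] <- n_time - base * (heads - 1L)
  slices <- split(seq_len(n_time), rep(seq_len(heads), widths))
  list(n_roi = as.integer(n_roi), n_time = as.integer(n_time),
       heads = heads, widths = widths, slices = slices,
       hidden = n_time %/% 2L)
}

sat_init <- function(config) {
  q <- config$n_time
  list(
    wq = matrix(rnorm(q * q, sd = sqrt(1 / q)), q, q), bq = rep(0, q),
    wk = matrix(rnorm((q + 4) * q, sd = sqrt(1 / (q + 4))), q + 4, q), bk = rep(0, q),
    wv = matrix(rnorm((q + 4) * q, sd = sqrt(1 / (q + 4))), q + 4, q), bv = rep(0, q),
    wo = matrix(rnorm(q * q, sd = sqrt(1 / q)), q, q), bo = rep(0, q),
    ln = ln_init(q),
    dm = matrix(rnorm(q * config$hidden, sd = sqrt(2 / q)), q, config$hidden),
    dmb = rep(0, config$hidden),
    um = matrix(rnorm(config$hidden * q, sd = sqrt(1 / config$hidden)),
                config$hidden, q),
    umb = rep(0, q))
}

#' Project rough features to attention queries, keys and values
#'
#' Queries are a linear map of the rough features; keys and values are linear
#' maps of the rough features concatenated with the four ROI embedding
#' columns (input width `n_time + 4`).
#'
#' @param f1 rough feature matrix (`n_roi` x `n_time`).
#' @param emb ROI embedding matrix (`n_roi` x 4).
#' @param params attention parameters (see [sat_config()] / internals).
#' @return list with `n_roi` x `n_time` matrices `q`, `k`, `v`.
#' @export
project_qkv <- function(f1, emb, params) {
  if (nrow(f1) != nrow(emb)) stop_shape("f1 and emb disagree on n_roi")
  faug <- cbind(f1, emb)
  list(q = sweep(f1 %*% params$wq, 2L, params$bq, `+`),
       k = sweep(faug %*% params$wk, 2L, params$bk, `+`),
       v = sweep(faug %*% params$wv, 2L, params$bv, `+`))
}

#' Scaled dot-product attention for one head
#'
#' `softmax(Qi %*% t(Ki) / sqrt(d)) %*% Vi` with `d` the head width; every
#' attention row is a probability vector over ROIs.
#'
#' @param qi,ki,vi per-head matrices (`n_roi` x head width).
#' @return list with the head output `out` and the attention matrix `attn`.
#' @export
central_attention <- function(qi, ki, vi) {
  if (!all(dim(qi) == dim(ki)) || nrow(vi) != nrow(qi))
    stop_shape("head matrices disagree")
  scores <- tcrossprod(qi, ki) / sqrt(ncol(qi))
  attn <- softmax_rows(scores)
  list(out = attn %*% vi, attn = attn)
}

sat_fwd <- function(f1, emb, params, config) {
  qkv <- project_qkv(f1, emb, params)
  heads <- lapply(config$slices, function(idx)
    central_attention(qkv$q[, idx, drop = FALSE],
                      qkv$k[, idx, drop = FALSE],
                      qkv$v[, idx, drop = FALSE]))
  ca <- do.call(cbind, lapply(heads, `[[`, "out"))
  o <- sweep(ca %*% params$wo, 2L, params$bo, `+`)
  r <- o + f1
  ln <- ln_fwd(r, params$ln)
  smca <- ln$y
  hpre <- sweep(smca %*% params$dm, 2L, params$dmb, `+`)
  h <- pmax(hpre, 0)
  u <- sweep(h %*% params$um, 2L, params$umb, `+`)
  fg <- u + smca
  list(fg = fg, smca = smca,
       cache = list(f1 = f1, emb = emb, qkv = qkv, heads = heads, ca = ca,
                    ln_cache = ln$cache, smca = smca, h = h,
                    mask = hpre > 0))
}

sat_bwd <- function(dfg, cache, params, config) {
  h <- cache$h
  dum <- crossprod(h, dfg)
  dumb <- colSums(dfg)
  dh <- (dfg %*% t(params$um)) * cache$mask
  ddm <- crossprod(cache$smca, dh)
  ddmb <- colSums(dh)
  dsmca <- dfg + dh %*% t(params$dm)
  lnb <- ln_bwd(dsmca, cache$ln_cache, params$ln)
  dr <- lnb$dx
  df1 <- dr
  dca <- dr %*% t(params$wo)
  dwo <- crossprod(cache$ca, dr)
  dbo <- colSums(dr)
  q <- config$n_time
  dq <- dk <- dv <- matrix(0, config$n_roi, q)
  for (hidx in seq_along(config$slices)) {
    idx <- config$slices[[hidx]]
    hd <- cache$heads[[hidx]]
    attn <- hd$attn
    vi <- cache$qkv$v[, idx, drop = FALSE]
    dout <- dca[, idx, drop = FALSE]
    dattn <- tcrossprod(dout, vi)
    dv[, idx] <- crossprod(attn, dout)
    dscore <- attn * (dattn - rowSums(dattn * attn))
    scale <- 1 / sqrt(length(idx))
    dq[, idx] <- (dscore %*% cache$qkv$k[, idx, drop = FALSE]) * scale
    dk[, idx] <- (crossprod(dscore, cache$qkv$q[, idx, drop = FALSE])) * scale
  }
  f1 <- cache$f1
  faug <- cbind(f1, cache$emb)
  dwq <- crossprod(f1, dq); dbq <- colSums(dq)
  dwk <- crossprod(faug, dk); dbk <- colSums(dk)
  dwv <- crossprod(faug, dv); dbv <- colSums(dv)
  df1 <- df1 + dq %*% t(params$wq) +
    (dk %*% t(params$wk))[, seq_len(q), drop = FALSE] +
    (dv %*% t(params$wv))[, seq_len(q), drop = FALSE]
  list(df1 = df1,
       grads = list(wq = dwq, bq = dbq, wk = dwk, bk = dbk,
                    wv = dwv, bv = dbv, wo = dwo, bo = dbo,
                    ln = list(gain = lnb$dgain, bias = lnb$dbias),
                    dm = ddm, dmb = ddmb, um = dum, umb = dumb))
}
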