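#' Rank ROI importance by shielding
#'
#' Shields one ROI at a time — zeroing its row of the time-series matrix and
#' its row/column of the connectivity matrix (diagonal kept 1) — and
#' recomputes classification accuracy on the supplied subjects. Sorting the
#' shielded accuracies in ascending order ranks the ROIs by importance: the
#' larger the accuracy drop, the more the classifier depended on that ROI.
#'
#' @param model a trained `fbn_model`.
#' @param study a `phantom_study` (or subject list with an `emb` attribute).
#' @param path prediction path (see [predict_study()]).
#' @return data.frame with one row per ROI, sorted by ascending shielded
#'   accuracy (ties broken by ROI index): columns `roi`, `acc_shielded`,
#'   `acc_drop`. The unshielded accuracy is attached as attribute
#'   `baseline_acc`.
#' @export
roi_importance <- function(model, study, path = "both") {
  n <- model$config$n_roi
  positive <- model$config$classes[model$config$n_classes]
  emb <- study$emb
  subjects <- study$subjects
  cls <- vapply(subjects, `[[`, "", "class")
  # run the generator once per subject; shielding only edits its outputs
  gens <- if (path %in% c("both", "generated"))
    lapply(subjects, function(s) construct_fbn(model, s$volume, study$atlas))
  else vector("list", length(subjects))
  acc_of <- function(shield) {
    probs <- t(vapply(seq_along(subjects), function(i)
      predict_subject(model, subjects[[i]], emb, path, shield, gens[[i]]),
      numeric(model$config$n_classes)))
    pred <- model$config$classes[max.col(probs, ties.method = "first")]
    suppressWarnings(compute_metrics(pred, cls, positive)$acc)
  }
  base <- acc_of(NULL)
  accs <- vapply(seq_len(n), acc_of, 0)
  out <- data.frame(roi = seq_len(n), acc_shielded = accs,
                    acc_drop = base - accs)
  out <- out[order(out$acc_shielded, out$roi), ]
  rownames(out) <- NULL
  attr(out, "baseline_acc") <- base
  out
}

#' Altered connectivity between two groups of networks
#'
#' Computes the difference of group-mean connectivity matrices
#' `D = mean(group A) - mean(group B)`; negative entries are connections
#' reduced from A to B, positive entries increased. The 90% quantile of the
#' absolute off-diagonal differences (upper triangle, each unordered pair
#' once; linear-interpolation quantile) is the significance threshold;
#' surviving edges are partitioned by sign. The strongest alterations are
#' summarized as the top `top_frac` (default 2%) of edges and the top
#' `top_n` (default 5) reduced and increased connections, ranked by absolute
#' difference with ties broken lexicographically by (i, j).
#'
#' @param group_a,group_b lists of `n_roi` x `n_roi` connectivity matrices.
#' @param quantile_prob threshold quantile on absolute altered strength.
#' @param top_frac fraction of edges in the "largest alterations" list.
#' @param top_n length of the per-direction strongest-edge lists.
#' @return an `altered_connectivity` list: `difference` matrix, `threshold`,
#'   edge data.frames `reduced`, `increased`, `top_edges`, `top_reduced`,
#'   `top_increased` (columns `i`, `j`, `difference`).
#' @export
altered_connectivity <- function(group_a, group_b, quantile_prob = 0.9,
                                 top_frac = 0.02, top_n = 5L) {
  if (!length(group_a) || !length(group_b))
    stop("both groups need at least one matrix", call. = FALSE)
  dims <- dim(group_a[[1]])
  for (m in c(group_a, group_b))
    if (!identical(dim(m), dims))
      stop("all matrices must share dimensions", call. = FALSE)
  mean_mat <- function(g) Reduce(`+`, g) / length(g)
  d <- mean_mat(group_a) - mean_mat(group_b)
  n <- nrow(d)
  ut <- which(upper.tri(d), arr.ind = TRUE)
  edges <- data.frame(i = ut[, 1], j = ut[, 2],
                      difference = d[upper.tri(d)])
  edges <- edges[order(edges$i, edges$j), ]
  thr <- unname(quantile(abs(edges$difference), quantile_prob, type = 7))
  surv <- edges[abs(edges$difference) >= thr & edges$difference != 0, ]
  rank_edges <- function(e) {
    e[order(-abs(e$difference), e$i, e$j), , drop = FALSE]
  }
  n_top <- max(1L, ceiling(top_frac * nrow(edges)))
  top_edges <- head(rank_edges(edges[edges$difference != 0, , drop = FALSE]),
                    n_top)
  reduced <- rank_edges(surv[surv$difference < 0, , drop = FALSE])
  increased <- rank_edges(surv[surv$difference > 0, , drop = FALSE])
  structure(list(difference = d, threshold = thr,
                 reduced = reduced, increased = increased,
                 top_edges = top_edges,
                 top_reduced = head(reduced, top_n),
                 top_increased = head(increased, top_n)),
            class = "altered_connectivity")
}

#' @export
print.altered_connectivity <- function(x, ...) {
  cat("altered connectivity:", nrow(x$reduced), "reduced and",
      nrow(x$increased), "increased edges above the",
      sprintf("%.4g", x$threshold), "threshold\n")
  invisible(x)
}
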