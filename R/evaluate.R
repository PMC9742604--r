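#' Classification metrics from binary predictions
#'
#' Accuracy, sensitivity, specificity and F1 from an explicit confusion
#' table. By package convention the "positive" class is the later disease
#' stage of the pairwise task. A division by zero (e.g., no positives in
#' truth) yields 0 with a warning.
#'
#' @param predictions character/factor vector of predicted labels.
#' @param truths vector of true labels.
#' @param positive the positive class label; defaults to the second sorted
#'   unique truth label.
#' @return list with `acc`, `sen`, `spe`, `f1` and the confusion counts
#'   `tp`, `tn`, `fp`, `fn`.
#' @examples
#' compute_metrics(c("B", "A", "B"), c("B", "A", "A"), positive = "B")
#' @export
compute_metrics <- function(predictions, truths, positive = NULL) {
  if (length(predictions) == 0) stop("empty input", call. = FALSE)
  if (length(predictions) != length(truths))
    stop("predictions and truths differ in length", call. = FALSE)
  predictions <- as.character(predictions)
  truths <- as.character(truths)
  if (is.null(positive)) positive <- sort(unique(truths))[
    min(2L, length(unique(truths)))]
  tp <- sum(predictions == positive & truths == positive)
  tn <- sum(predictions != positive & truths != positive)
  fp <- sum(predictions == positive & truths != positive)
  fn <- sum(predictions != positive & truths == positive)
  div <- function(num, den, what) {
    if (den == 0) { warning(what, ": division by zero, returning 0"); 0 }
    else num / den
  }
  acc <- (tp + tn) / length(truths)
  sen <- div(tp, tp + fn, "sensitivity")
  spe <- div(tn, tn + fp, "specificity")
  prec <- div(tp, tp + fp, "precision")
  f1 <- if (prec + sen == 0) { warning("F1: division by zero, returning 0"); 0 }
        else 2 * prec * sen / (prec + sen)
  list(acc = acc, sen = sen, spe = spe, f1 = f1,
       tp = tp, tn = tn, fp = fp, fn = fn)
}

#' Stratified k-fold assignment
#'
#' @param classes vector of class labels, one per subject.
#' @param folds number of folds.
#' @param seed shuffle seed.
#' @return integer vector of fold ids (1..folds), one per subject; every
#'   class is spread across folds round-robin after a seeded shuffle.
#' @export
stratified_folds <- function(classes, folds = 5L, seed = 1L) {
  tab <- table(classes)
  if (any(tab < folds))
    stop("every class needs at least as many subjects as folds", call. = FALSE)
  fold <- integer(length(classes))
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(classes == cl))
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  fold
}

#' Repeated stratified cross-validation of the full pipeline
#'
#' For each repeat, subjects are shuffled into stratified folds; a fresh
#' model is trained on each training split and evaluated on the held-out
#' fold. Metrics are averaged with their standard error over all
#' `folds * repeats` evaluations.
#'
#' @param study a `phantom_study`.
#' @param model_config an [fbn_config()] (defaults to one matched to the
#'   study's spec).
#' @param trn_config a [train_config()].
#' @param folds number of folds (reference protocol: 5).
#' @param repeats number of repeats (reference protocol: 10).
#' @param path prediction path passed to [predict_study()].
#' @param seed master seed; fold shuffles and model initializations derive
#'   from it.
#' @param permute_labels permute class labels once per repeat before
#'   training (chance-level control).
#' @return an `fbn_cv` list: `fold_metrics` (data.frame with one row per
#'   fold x repeat), `summary` (mean and standard error per metric), and
#'   `predictions`.
#' @export
cross_validate <- function(study, model_config = fbn_config_for_spec(study$spec),
                           trn_config = train_config(), folds = 5L,
                           repeats = 10L, path = "both", seed = 1L,
                           permute_labels = FALSE) {
  subjects <- study$subjects
  classes <- vapply(subjects, `[[`, "", "class")
  positive <- model_config$classes[length(model_config$classes)]
  rows <- list()
  preds_all <- list()
  for (r in seq_len(repeats)) {
    cl_r <- classes
    if (permute_labels)
      cl_r <- with_seed(derive_seed(seed, 5000L + r), sample(classes))
    fold <- stratified_folds(cl_r, folds, derive_seed(seed, 100L + r))
    for (f in seq_len(folds)) {
      train_idx <- which(fold != f)
      test_idx <- which(fold == f)
      sub_train <- study
      sub_train$subjects <- Map(function(s, cl) { s$class <- cl; s },
                                subjects[train_idx], cl_r[train_idx])
      model <- fbn_model(model_config, seed = derive_seed(seed, 200L + 10L * r + f))
      tc <- trn_config
      tc$seed <- derive_seed(seed, 300L + 10L * r + f)
      fit <- train_model(model, sub_train, tc)
      sub_test <- study
      sub_test$subjects <- subjects[test_idx]
      pr <- predict_study(fit$model, sub_test, path = path)
      pr$class <- cl_r[test_idx]
      pr$repeat_id <- r; pr$fold <- f
      m <- compute_metrics(pr$predicted, pr$class, positive)
      rows[[length(rows) + 1L]] <-
        data.frame(repeat_id = r, fold = f, acc = m$acc, sen = m$sen,
                   spe = m$spe, f1 = m$f1, n_test = length(test_idx))
      preds_all[[length(preds_all) + 1L]] <- pr
    }
  }
  fold_metrics <- do.call(rbind, rows)
  met <- c("acc", "sen", "spe", "f1")
  summary <- data.frame(
    metric = met,
    mean = vapply(met, function(m) mean(fold_metrics[[m]]), 0),
    se = vapply(met, function(m)
      sd(fold_metrics[[m]]) / sqrt(nrow(fold_metrics)), 0))
  structure(list(fold_metrics = fold_metrics, summary = summary,
                 predictions = do.call(rbind, preds_all),
                 positive = positive),
            class = "fbn_cv")
}

#' @export
print.fbn_cv <- function(x, ...) {
  cat("cross-validated metrics (positive class:", x$positive, ")\n")
  s <- x$summary
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-4s %5.1f%% +/- %.1f\n", toupper(s$metric[i]),
                100 * s$mean[i], 100 * s$se[i]))
  invisible(x)
}
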