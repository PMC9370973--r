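# Literature comparators: the fixed-threshold pulse-similarity classifier and
# the pulse-wise skewness-only SVM.

#' Equal-sensitivity/specificity threshold
#'
#' Chooses the decision threshold for a score (predict positive when
#' score >= threshold) that minimizes |sensitivity - specificity| on the
#' training data. Candidates are the midpoints between consecutive sorted
#' unique scores plus sentinels below and above all scores; ties are broken
#' toward the smaller threshold.
#'
#' @param scores training scores (e.g. SigSim values).
#' @param labels training outcome factor (neg/pos, see [task_outcome()]).
#' @return the fitted threshold (numeric scalar).
#' @export
fit_equal_sens_spec_threshold <- function(scores, labels) {
  labels <- factor(labels, levels = c("neg", "pos"))
  if (nlevels(droplevels(labels)) < 2L)
    stop_task("both classes must be present to fit a threshold")
  u <- sort(unique(scores))
  if (length(u) == 1L) {
    warning("all scores identical; degenerate threshold at that value")
    return(u)
  }
  cand <- c(u[1L] - 1, (u[-length(u)] + u[-1L]) / 2, u[length(u)] + 1)
  n_pos <- sum(labels == "pos"); n_neg <- sum(labels == "neg")
  gap <- vapply(cand, function(th) {
    sens <- sum(scores >= th & labels == "pos") / n_pos
    spec <- sum(scores < th & labels == "neg") / n_neg
    abs(sens - spec)
  }, numeric(1))
  cand[which.min(gap)]  # which.min takes the first (smallest) on ties
}

#' Pulse-similarity threshold baseline
#'
#' The similarity-threshold comparator: a single SigSim feature classified by
#' a fixed threshold fitted on the training partition with the
#' equal-sensitivity/specificity criterion, then evaluated on the test
#' partition.
#'
#' @param train_scores,train_labels training SigSim values and neg/pos labels.
#' @param test_scores,test_labels test SigSim values and neg/pos labels.
#' @return list with `threshold` and `metrics` (a `metrics_report`).
#' @export
sigsim_threshold_baseline <- function(train_scores, train_labels,
                                      test_scores, test_labels) {
  th <- fit_equal_sens_spec_threshold(train_scores, train_labels)
  pred <- factor(ifelse(test_scores >= th, "pos", "neg"),
                 levels = c("neg", "pos"))
  list(threshold = th,
       metrics = evaluate_scores(test_scores, pred, test_labels))
}

#' Pulse-wise skewness SVM baseline
#'
#' The skewness-only comparator: an SVM trained on the single `Skewness`
#' quality index with the same cross-validated hyperparameter search as the
#' main classifiers, evaluated identically.
#'
#' @param train_x,test_x feature tables containing a `Skewness` column.
#' @param train_y,test_y neg/pos outcome factors.
#' @param cv_folds,opt_iters,seed,search passed to [train_quality_model()].
#' @return list with `model` (a `quality_model`) and `metrics`.
#' @export
skewness_svm_baseline <- function(train_x, train_y, test_x, test_y,
                                  cv_folds = 10, opt_iters = 30, seed = 1,
                                  search = "smbo") {
  for (d in list(train_x, test_x))
    if (!"Skewness" %in% colnames(as.data.frame(d)))
      stop_config("feature table lacks the 'Skewness' column")
  tr <- as.data.frame(train_x)[, "Skewness", drop = FALSE]
  te <- as.data.frame(test_x)[, "Skewness", drop = FALSE]
  model <- train_quality_model(tr, train_y, family = "svm",
                               cv_folds = cv_folds, opt_iters = opt_iters,
                               seed = seed, search = search)
  list(model = model, metrics = evaluate_model(model, te, test_y))
}
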