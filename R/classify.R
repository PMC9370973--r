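# Quality-classification tasks (BQ / HQ1 / HQ2), subject-wise splitting,
# hyperparameter-tuned training of six model families, the cascade, and the
# eight-metric evaluation report.

#' Quality classification task specification
#'
#' Three binary tasks are defined over the B/F/E consensus labels:
#' \describe{
#'   \item{BQ}{Basic quality: F and E (usable for heart rate) vs B.}
#'   \item{HQ1}{High quality, single stage: E vs B and F.}
#'   \item{HQ2}{High quality, cascaded: E vs F, consuming only pulses the BQ
#'     stage passes (F/E pulses).}
#' }
#'
#' @param name one of `"BQ"`, `"HQ1"`, `"HQ2"`.
#' @return object of class `task_spec` with `positive` and `negative` label
#'   sets.
#' @export
quality_task <- function(name = c("BQ", "HQ1", "HQ2")) {
  name <- match.arg(name)
  spec <- switch(name,
    BQ  = list(positive = c("F", "E"), negative = "B"),
    HQ1 = list(positive = "E", negative = c("B", "F")),
    HQ2 = list(positive = "E", negative = "F"))
  structure(c(list(name = name), spec), class = "task_spec")
}

#' Map consensus labels to a task's binary outcome
#'
#' @param task a `task_spec`.
#' @param labels character vector of B/F/E labels.
#' @return factor with levels `c("neg", "pos")`; labels outside the task
#'   (e.g. B for HQ2) become NA and should be dropped by the caller.
#' @export
task_outcome <- function(task, labels) {
  stopifnot(inherits(task, "task_spec"))
  out <- rep(NA_character_, length(labels))
  out[labels %in% task$positive] <- "pos"
  out[labels %in% task$negative] <- "neg"
  factor(out, levels = c("neg", "pos"))
}

#' Subject-wise train/test split
#'
#' Shuffles the subject ids with the given seed and assigns the first
#' `round-half-up(train_frac * n)` subjects to the training set, so no
#' subject contributes pulses to both partitions.
#'
#' @param subjects vector of unique subject ids.
#' @param train_frac training fraction.
#' @param seed integer seed.
#' @return list with `train` and `test` subject id vectors.
#' @export
split_subjectwise <- function(subjects, train_frac = 0.7, seed = 1) {
  subjects <- unique(as.character(subjects))
  if (length(subjects) < 2L) stop_parameter("need at least 2 subjects to split")
  n_train <- floor(train_frac * length(subjects) + 0.5)
  set.seed(derive_seed(seed, 42L))
  perm <- sample(subjects)
  list(train = sort(perm[seq_len(n_train)]),
       test = sort(perm[-seq_len(n_train)]))
}

## ---- hyperparameter search spaces ----------------------------------------

quality_families <- c("tree", "naive_bayes", "svm", "knn", "ensemble",
                      "neural_net")

family_space <- function(family) {
  switch(family,
    tree = list(
      maxdepth = list(type = "int", lo = 1, hi = 30, log = FALSE),
      minbucket = list(type = "int", lo = 1, hi = 64, log = TRUE)),
    naive_bayes = list(
      distribution = list(type = "cat", levels = c("gaussian", "kernel"))),
    svm = list(
      kernel = list(type = "cat",
                    levels = c("linear", "quadratic", "cubic", "rbf")),
      cost = list(type = "num", lo = 1e-3, hi = 1e3, log = TRUE),
      gamma = list(type = "num", lo = 1e-2, hi = 1e2, log = TRUE)),
    knn = list(
      k = list(type = "int", lo = 1, hi = 64, log = TRUE),
      metric = list(type = "cat", levels = c("euclidean", "manhattan")),
      vote = list(type = "cat", levels = c("uniform", "distance"))),
    ensemble = list(
      method = list(type = "cat", levels = c("bagging", "boosting")),
      n_learners = list(type = "int", lo = 50, hi = 500, log = FALSE),
      learn_rate = list(type = "num", lo = 1e-2, hi = 1, log = TRUE)),
    neural_net = list(
      size = list(type = "int", lo = 4, hi = 128, log = TRUE),
      decay = list(type = "num", lo = 1e-6, hi = 1e-1, log = TRUE)),
    stop_parameter("unknown model family '%s'", family))
}

sample_params <- function(space) {
  out <- list()
  for (nm in names(space)) {
    s <- space[[nm]]
    out[[nm]] <- switch(s$type,
      cat = sample(s$levels, 1L),
      int = {
        v <- if (s$log) exp(stats::runif(1, log(s$lo), log(s$hi)))
             else stats::runif(1, s$lo, s$hi + 1)
        max(s$lo, min(s$hi, as.integer(round(v))))
      },
      num = if (s$log) exp(stats::runif(1, log(s$lo), log(s$hi)))
            else stats::runif(1, s$lo, s$hi))
  }
  out
}

params_to_row <- function(space, params) {
  row <- lapply(names(space), function(nm) {
    s <- space[[nm]]
    if (s$type == "cat") factor(params[[nm]], levels = s$levels)
    else if (s$log) log(as.numeric(params[[nm]]))
    else as.numeric(params[[nm]])
  })
  names(row) <- names(space)
  as.data.frame(row)
}

## ---- family fit / predict -------------------------------------------------

fit_family <- function(family, params, x, y) {
  x <- as.data.frame(x)
  fit <- switch(family,
    tree = rpart::rpart(y ~ ., data = cbind(x, y = y), method = "class",
                        control = rpart::rpart.control(
                          maxdepth = params$maxdepth,
                          minbucket = params$minbucket, cp = 0,
                          xval = 0)),
    naive_bayes = if (params$distribution == "gaussian")
        e1071::naiveBayes(x, y)
      else kernel_nb_fit(x, y),
    svm = {
      kern <- switch(params$kernel, linear = "linear", rbf = "radial",
                     quadratic = "polynomial", cubic = "polynomial")
      deg <- switch(params$kernel, quadratic = 2L, cubic = 3L, 1L)
      e1071::svm(as.matrix(x), y, kernel = kern, degree = deg,
                 cost = params$cost, gamma = params$gamma, coef0 = 1,
                 scale = FALSE)
    },
    knn = list(x = as.matrix(x), y = y, k = params$k,
               metric = params$metric, vote = params$vote),
    ensemble = if (params$method == "bagging")
        randomForest::randomForest(x, y, ntree = params$n_learners)
      else xgboost::xgb.train(
        params = list(eta = params$learn_rate, max_depth = 3L,
                      objective = "binary:logistic", nthread = 1L),
        data = xgboost::xgb.DMatrix(as.matrix(x),
                                    label = as.integer(y == "pos")),
        nrounds = min(params$n_learners, 300L), verbose = 0),
    neural_net = nnet::nnet(as.matrix(x), class.ind2(y), size = params$size,
                            decay = params$decay, maxit = 200, trace = FALSE,
                            MaxNWts = 10000, softmax = FALSE,
                            entropy = TRUE))
  list(family = family, params = params, fit = fit, features = colnames(x))
}

class.ind2 <- function(y) as.numeric(y == "pos")

# positive-class score: a probability where the family provides one, a signed
# margin for the SVM
predict_family <- function(model, x) {
  x <- as.data.frame(x)[, model$features, drop = FALSE]
  switch(model$family,
    tree = unname(predict(model$fit, x, type = "prob")[, "pos"]),
    naive_bayes = if (inherits(model$fit, "naiveBayes")) {
        unname(predict(model$fit, x, type = "raw")[, "pos"])
      } else kernel_nb_predict(model$fit, x),
    svm = {
      dv <- attr(predict(model$fit, as.matrix(x), decision.values = TRUE),
                 "decision.values")
      # e1071 orients the decision value toward the first label it saw
      sgn <- if (colnames(dv)[1L] %in% c("pos/neg")) 1 else -1
      as.numeric(dv[, 1L]) * sgn
    },
    knn = knn_weighted(model$fit$x, model$fit$y, as.matrix(x),
                       k = model$fit$k, metric = model$fit$metric,
                       vote = model$fit$vote)$score,
    ensemble = if (inherits(model$fit, "randomForest"))
        unname(predict(model$fit, x, type = "prob")[, "pos"])
      else as.numeric(predict(model$fit, xgboost::xgb.DMatrix(as.matrix(x)))),
    neural_net = as.numeric(predict(model$fit, as.matrix(x))))
}

score_threshold <- function(family) if (family == "svm") 0 else 0.5

## ---- kernel-density naive Bayes (no packaged implementation available) ----

kernel_nb_fit <- function(x, y) {
  lev <- levels(y)
  dens <- lapply(lev, function(lv) {
    lapply(x[y == lv, , drop = FALSE], function(col) {
      d <- stats::density(col, n = 512)
      list(x = d$x, y = pmax(d$y, 1e-9))
    })
  })
  names(dens) <- lev
  structure(list(densities = dens,
                 prior = table(y) / length(y), levels = lev),
            class = "ppgqc_kernel_nb")
}

kernel_nb_predict <- function(fit, x) {
  loglik <- sapply(fit$levels, function(lv) {
    ll <- rep(log(as.numeric(fit$prior[lv])), nrow(x))
    for (j in seq_along(x)) {
      d <- fit$densities[[lv]][[j]]
      f <- stats::approx(d$x, d$y, xout = x[[j]], rule = 2)$y
      ll <- ll + log(pmax(f, 1e-9))
    }
    ll
  })
  m <- apply(loglik, 1L, max)
  post <- exp(loglik - m)
  unname(post[, "pos"] / rowSums(post))
}

## ---- cross-validated loss and sequential model-based optimization ---------

cv_loss <- function(family, params, x, y, folds, fold_id) {
  losses <- vapply(seq_len(folds), function(k) {
    tr <- fold_id != k
    if (min(table(y[tr])) < 1L || !any(!tr)) return(NA_real_)
    m <- fit_family(family, params, x[tr, , drop = FALSE], y[tr])
    s <- predict_family(m, x[!tr, , drop = FALSE])
    pred <- ifelse(s >= score_threshold(family), "pos", "neg")
    mean(pred != y[!tr])
  }, numeric(1))
  mean(losses, na.rm = TRUE)
}

#' Train one quality-classifier family with tuned hyperparameters
#'
#' Tunes the family's hyperparameters by minimizing the ten-fold
#' cross-validated misclassification rate on the training pulses over at most
#' `opt_iters` sequential evaluations. The default search is model-based:
#' after an initial random stage, a random-forest surrogate fitted to the
#' evaluated configurations proposes the next candidate by expected
#' improvement; `search = "random"` evaluates random draws only. The best
#' configuration is refitted on the full training partition.
#'
#' @param x training feature matrix/data.frame (already conditioned).
#' @param y binary outcome factor with levels `c("neg", "pos")` (see
#'   [task_outcome()]).
#' @param family one of `"tree"`, `"naive_bayes"`, `"svm"`, `"knn"`,
#'   `"ensemble"`, `"neural_net"`.
#' @param cv_folds cross-validation folds.
#' @param opt_iters total hyperparameter evaluations.
#' @param seed integer seed.
#' @param search `"smbo"` (surrogate-guided) or `"random"`.
#' @param task optional `task_spec` stored with the model.
#' @return object of class `quality_model`.
#' @export
train_quality_model <- function(x, y, family = "svm", cv_folds = 10,
                                opt_iters = 30, seed = 1,
                                search = c("smbo", "random"), task = NULL) {
  search <- match.arg(search)
  family <- match.arg(family, quality_families)
  x <- as.data.frame(x)
  y <- as.factor(y)
  y <- droplevels(y)
  if (nlevels(y) != 2L) stop_task("training outcome must have exactly 2 classes present")
  if (!identical(levels(y), c("neg", "pos"))) levels(y) <- c("neg", "pos")
  if (min(table(y)) < cv_folds) cv_folds <- max(2L, min(table(y)))
  space <- family_space(family)
  set.seed(derive_seed(seed, 7L))
  fold_id <- stratified_folds(y, cv_folds)

  history <- list()
  losses <- numeric(0)
  n_init <- if (search == "random") opt_iters else min(max(5L, 3L), opt_iters)
  for (i in seq_len(opt_iters)) {
    if (i <= n_init || search == "random") {
      cand <- sample_params(space)
    } else {
      # surrogate: random forest over evaluated configs; expected improvement
      # from the per-tree prediction spread
      H <- do.call(rbind, lapply(history, function(h) params_to_row(space, h)))
      rf <- randomForest::randomForest(H, losses, ntree = 200)
      pool <- replicate(200, sample_params(space), simplify = FALSE)
      Pm <- do.call(rbind, lapply(pool, function(h) params_to_row(space, h)))
      pr <- predict(rf, Pm, predict.all = TRUE)
      mu <- pr$aggregate
      sdv <- apply(pr$individual, 1L, stats::sd)
      best <- min(losses)
      z <- (best - mu) / pmax(sdv, 1e-9)
      ei <- (best - mu) * stats::pnorm(z) + pmax(sdv, 1e-9) * stats::dnorm(z)
      cand <- pool[[which.max(ei)]]
    }
    loss <- suppressWarnings(cv_loss(family, cand, x, y, cv_folds, fold_id))
    if (!is.finite(loss)) loss <- 1
    history[[i]] <- cand
    losses[i] <- loss
  }
  best <- which.min(losses)
  final <- fit_family(family, history[[best]], x, y)
  structure(list(
    family = family, task = task, hyperparameters = history[[best]],
    cv_loss = losses[best], search = search, model = final,
    features = colnames(x), threshold = score_threshold(family)
  ), class = "quality_model")
}

#' @export
print.quality_model <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, function(v) format(v, digits = 4),
                     character(1)),
              sep = "=", collapse = ", ")
  cat(sprintf("<quality_model> %s%s: CV loss %.4f; %s\n", x$family,
              if (!is.null(x$task)) paste0(" [", x$task$name, "]") else "",
              x$cv_loss, hp))
  invisible(x)
}

#' Predict scores or labels from a trained quality model
#'
#' @param object a `quality_model`.
#' @param newdata feature matrix/data.frame containing the model's features.
#' @param type `"score"` (probability or signed margin) or `"label"`
#'   (factor neg/pos at the model's natural threshold).
#' @param ... unused.
#' @export
predict.quality_model <- function(object, newdata, type = c("score", "label"),
                                  ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  missing <- setdiff(object$features, colnames(newdata))
  if (length(missing))
    stop_integrity("input lacks model feature(s): %s", paste(missing, collapse = ", "))
  s <- predict_family(object$model, newdata[, object$features, drop = FALSE])
  if (type == "score") return(s)
  factor(ifelse(s >= object$threshold, "pos", "neg"), levels = c("neg", "pos"))
}

#' Cascaded three-way prediction
#'
#' Applies the Basic-quality model first: BQ-negative pulses are labelled B
#' regardless of the second stage. BQ-positive pulses are passed to the
#' Type-2 High-quality model: HQ2-negative means F, HQ2-positive means
#' E-eligible (reported as E).
#'
#' @param bq,hq2 trained `quality_model`s for the BQ and HQ2 tasks.
#' @param newdata feature table covering both models' features. When the two
#'   stages were trained on differently conditioned matrices (each task fits
#'   its own Box-Cox/z-score parameters), pass the raw SQI table here together
#'   with each stage's training transform so every model sees inputs on the
#'   scale it was trained on.
#' @param bq_transform,hq2_transform optional per-stage parameter tables from
#'   [boxcox_zscore()] applied to `newdata` before the respective model.
#' @return factor with levels `c("B", "F", "E")` (E meaning E-eligible).
#' @export
cascade_predict <- function(bq, hq2, newdata, bq_transform = NULL,
                            hq2_transform = NULL) {
  stopifnot(inherits(bq, "quality_model"), inherits(hq2, "quality_model"))
  newdata <- as.data.frame(newdata)
  condition <- function(params) {
    if (is.null(params)) return(newdata)
    as.data.frame(apply_boxcox_zscore(as.matrix(newdata[, params$feature,
                                                        drop = FALSE]),
                                      params))
  }
  bq_lab <- predict(bq, condition(bq_transform), type = "label")
  out <- rep("B", nrow(newdata))
  pass <- bq_lab == "pos"
  if (any(pass)) {
    hq_lab <- predict(hq2, condition(hq2_transform)[pass, , drop = FALSE],
                      type = "label")
    out[pass] <- ifelse(hq_lab == "pos", "E", "F")
  }
  factor(out, levels = c("B", "F", "E"))
}

## ---- metrics ---------------------------------------------------------------

#' Area under the ROC curve by rank statistic
#'
#' Mann-Whitney formulation with midrank tie handling: the probability that a
#' random positive scores above a random negative, counting ties as 1/2.
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels factor/logical/binary labels; the larger level is positive.
#' @return AUC in `[0, 1]`, or NA if only one class is present.
#' @export
auc_midrank <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores)  # midranks
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluation metrics from confusion counts
#'
#' @param tp,fp,tn,fn confusion-matrix counts.
#' @param auc optional AUC to carry along.
#' @return object of class `metrics_report` with AUC, Acc, Sens, Spec, Prec,
#'   MCC, F1, Cohen's kappa and the four counts.
#' @export
metrics_from_counts <- function(tp, fp, tn, fn, auc = NA_real_) {
  n <- tp + fp + tn + fn
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  prec <- tp / (tp + fp)
  acc <- (tp + tn) / n
  f1 <- 2 * prec * sens / (prec + sens)
  mcc_den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  mcc <- if (mcc_den == 0) NA_real_ else (tp * tn - fp * fn) / mcc_den
  po <- acc
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  kappa <- if (pe == 1) NA_real_ else (po - pe) / (1 - pe)
  structure(list(AUC = auc, Acc = acc, Sens = sens, Spec = spec, Prec = prec,
                 MCC = mcc, F1 = f1, kappa = kappa,
                 TP = tp, FP = fp, TN = tn, FN = fn),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> AUC %.4f  Acc %.4f  Sens %.4f  Spec %.4f  Prec %.4f  MCC %.4f  F1 %.4f  kappa %.4f\n",
    x$AUC, x$Acc, x$Sens, x$Spec, x$Prec, x$MCC, x$F1, x$kappa))
  cat(sprintf("  confusion: TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}

#' Evaluate scores and predicted labels against a binary truth
#'
#' @param scores continuous scores for the AUC.
#' @param predicted factor of predicted neg/pos labels.
#' @param truth factor of true neg/pos labels.
#' @return a `metrics_report`.
#' @export
evaluate_scores <- function(scores, predicted, truth) {
  truth <- factor(truth, levels = c("neg", "pos"))
  predicted <- factor(predicted, levels = c("neg", "pos"))
  tp <- sum(predicted == "pos" & truth == "pos")
  fp <- sum(predicted == "pos" & truth == "neg")
  tn <- sum(predicted == "neg" & truth == "neg")
  fn <- sum(predicted == "neg" & truth == "pos")
  auc <- if (nlevels(droplevels(truth)) < 2L) NA_real_
         else auc_midrank(scores, truth)
  metrics_from_counts(tp, fp, tn, fn, auc = auc)
}

#' Evaluate a trained model on a test partition
#'
#' @param model a `quality_model`.
#' @param x test features.
#' @param y test outcome factor (neg/pos).
#' @return a `metrics_report`.
#' @export
evaluate_model <- function(model, x, y) {
  s <- predict(model, x, type = "score")
  evaluate_scores(s, predict(model, x, type = "label"),
                  factor(y, levels = c("neg", "pos")))
}
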