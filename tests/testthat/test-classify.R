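test_that("task specifications partition the label alphabet", {
  bq <- quality_task("BQ")
  expect_setequal(bq$positive, c("F", "E")); expect_equal(bq$negative, "B")
  hq1 <- quality_task("HQ1")
  expect_equal(hq1$positive, "E"); expect_setequal(hq1$negative, c("B", "F"))
  hq2 <- quality_task("HQ2")
  y <- task_outcome(hq2, c("B", "F", "E"))
  expect_true(is.na(y[1]))  # B is outside the cascaded task
  expect_equal(as.character(y[2:3]), c("neg", "pos"))
  for (tn in c("BQ", "HQ1", "HQ2")) {
    tk <- quality_task(tn)
    expect_length(intersect(tk$positive, tk$negative), 0)
  }
})

test_that("subject-wise split rounds half up and never leaks", {
  s31 <- split_subjectwise(sprintf("S%02d", 1:31), seed = 1)
  expect_length(s31$train, 22L)
  expect_length(s31$test, 9L)
  s10 <- split_subjectwise(sprintf("S%02d", 1:10), seed = 1)
  expect_length(s10$train, 7L)
  expect_length(s10$test, 3L)
  expect_length(intersect(s10$train, s10$test), 0)
  expect_setequal(c(s10$train, s10$test), sprintf("S%02d", 1:10))
  expect_identical(split_subjectwise(sprintf("S%02d", 1:10), seed = 5),
                   split_subjectwise(sprintf("S%02d", 1:10), seed = 5))
})

test_that("metrics reproduce a hand confusion matrix and stay consistent", {
  m <- metrics_from_counts(tp = 50, fp = 10, tn = 90, fn = 50)
  expect_equal(m$Sens, 0.5)
  expect_equal(m$Spec, 0.9)
  expect_equal(m$Prec, 50 / 60, tolerance = 1e-9)
  expect_equal(m$Acc, 0.7)
  mcc_hand <- (50 * 90 - 10 * 50) / sqrt(60) / sqrt(100) / sqrt(100) / sqrt(140)
  expect_equal(m$MCC, mcc_hand, tolerance = 1e-9)
  po <- 0.7; pe <- (60 * 100 + 140 * 100) / 200^2
  expect_equal(m$kappa, (po - pe) / (1 - pe), tolerance = 1e-9)
  expect_equal(m$F1, 2 * m$Prec * m$Sens / (m$Prec + m$Sens), tolerance = 1e-9)
  # internal consistency on random confusion counts
  set.seed(26)
  for (i in 1:10) {
    cts <- as.list(rmultinom(1, 200, runif(4, 0.05, 1))[, 1])
    names(cts) <- c("tp", "fp", "tn", "fn")
    r <- do.call(metrics_from_counts, cts)
    n <- with(cts, tp + fp + tn + fn)
    expect_equal(r$Acc, (cts$tp + cts$tn) / n, tolerance = 1e-9)
    expect_equal(r$Sens, cts$tp / (cts$tp + cts$fn), tolerance = 1e-9)
    expect_equal(r$Spec, cts$tn / (cts$tn + cts$fp), tolerance = 1e-9)
  }
})

test_that("midrank AUC handles perfection, ties, and matches pROC", {
  y <- factor(rep(c("neg", "pos"), each = 5), levels = c("neg", "pos"))
  expect_equal(auc_midrank(c(1:5, 6:10), y), 1)
  expect_equal(auc_midrank(rep(1, 10), y), 0.5)
  set.seed(27)
  for (i in 1:5) {
    s <- rnorm(60)
    yy <- factor(sample(c("neg", "pos"), 60, TRUE), levels = c("neg", "pos"))
    ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(yy, s, quiet = TRUE,
                                                           direction = "<"))))
    expect_equal(auc_midrank(s, yy), ref, tolerance = 1e-9)
  }
  expect_true(is.na(auc_midrank(rnorm(5), factor(rep("pos", 5),
                                                 levels = c("neg", "pos")))))
})

test_that("evaluate_scores builds the report from predictions", {
  truth <- factor(c(rep("pos", 100), rep("neg", 100)), levels = c("neg", "pos"))
  pred <- factor(c(rep("pos", 50), rep("neg", 50),
                   rep("pos", 10), rep("neg", 90)), levels = c("neg", "pos"))
  r <- evaluate_scores(seq_len(200), pred, truth)
  expect_equal(c(r$TP, r$FP, r$TN, r$FN), c(50, 10, 90, 50))
  # perfect scores and predictions
  p <- evaluate_scores(c(rep(0, 100), rep(1, 100)),
                       factor(rep(c("neg", "pos"), each = 100),
                              levels = c("neg", "pos")),
                       factor(rep(c("neg", "pos"), each = 100),
                              levels = c("neg", "pos")))
  expect_equal(p$AUC, 1); expect_equal(p$MCC, 1); expect_equal(p$kappa, 1)
})

sep_problem <- function(n = 200, seed = 28) {
  set.seed(seed)
  y <- factor(rep(c("neg", "pos"), each = n / 2), levels = c("neg", "pos"))
  x <- data.frame(f1 = ifelse(y == "pos", 2, -2) + rnorm(n, 0, 0.3),
                  f2 = rnorm(n))
  list(x = x, y = y)
}

test_that("every family trains, predicts, and separates an easy task", {
  pb <- sep_problem()
  for (fam in c("tree", "naive_bayes", "svm", "knn", "ensemble", "neural_net")) {
    m <- train_quality_model(pb$x, pb$y, family = fam, cv_folds = 4,
                             opt_iters = 2, seed = 1, search = "random")
    r <- evaluate_model(m, pb$x, pb$y)
    expect_gte(r$Acc, 0.95, label = fam)
    expect_length(predict(m, pb$x), nrow(pb$x))
  }
})

test_that("the SVM family reaches near-zero CV loss on separable data", {
  pb <- sep_problem(n = 160)
  m <- train_quality_model(pb$x, pb$y, family = "svm", cv_folds = 5,
                           opt_iters = 4, seed = 2, search = "random")
  expect_lte(m$cv_loss, 0.02)
})

test_that("permuted labels collapse accuracy to the majority rate", {
  set.seed(29)
  n <- 150
  y <- factor(sample(rep(c("neg", "pos"), c(90, 60))), levels = c("neg", "pos"))
  x <- data.frame(f1 = rnorm(n), f2 = rnorm(n))
  m <- train_quality_model(x, y, family = "tree", cv_folds = 4, opt_iters = 2,
                           seed = 3, search = "random")
  xt <- data.frame(f1 = rnorm(100), f2 = rnorm(100))
  yt <- factor(sample(rep(c("neg", "pos"), c(60, 40))), levels = c("neg", "pos"))
  r <- evaluate_model(m, xt, yt)
  expect_lt(abs(r$Acc - 0.6), 0.125)
})

test_that("a single optimization iteration still yields a valid model", {
  pb <- sep_problem(n = 80)
  m <- train_quality_model(pb$x, pb$y, family = "knn", cv_folds = 3,
                           opt_iters = 1, seed = 4, search = "smbo")
  expect_s3_class(m, "quality_model")
  expect_true(all(predict(m, pb$x, type = "label") %in% c("neg", "pos")))
})

test_that("single-class training input raises a task error", {
  x <- data.frame(f1 = rnorm(20))
  y <- factor(rep("pos", 20), levels = c("neg", "pos"))
  expect_error(train_quality_model(x, y, family = "tree", opt_iters = 1),
               class = "ppgqc_task_error")
})

test_that("the cascade short-circuits BQ-negative pulses to B", {
  pb <- sep_problem(n = 200, seed = 30)
  bq <- train_quality_model(pb$x, pb$y, family = "svm", cv_folds = 3,
                            opt_iters = 2, seed = 5, search = "random")
  # HQ2 trained on a different boundary of the same features
  y2 <- factor(ifelse(pb$x$f2 > 0, "pos", "neg"), levels = c("neg", "pos"))
  hq2 <- train_quality_model(pb$x, y2, family = "tree", cv_folds = 3,
                             opt_iters = 2, seed = 6, search = "random")
  lab <- cascade_predict(bq, hq2, pb$x)
  bq_neg <- predict(bq, pb$x, type = "label") == "neg"
  expect_true(all(lab[bq_neg] == "B"))
  expect_true(all(lab[!bq_neg] %in% c("F", "E")))
  hq_pos <- predict(hq2, pb$x, type = "label") == "pos"
  expect_true(all(lab[!bq_neg & hq_pos] == "E"))
  # feature mismatch is an integrity error
  expect_error(predict(bq, pb$x[, "f1", drop = FALSE]),
               class = "ppgqc_integrity_error")
})
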