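# Feature conditioning (Box-Cox + z-score) and regularized neighborhood
# component analysis (NCA) with lambda tuning and stability selection.

#' Box-Cox transform and z-score a feature matrix
#'
#' Each feature column is shifted to strict positivity when needed
#' (shift = -min + 1e-6), Box-Cox transformed with its own
#' maximum-likelihood lambda (profile likelihood over `[-5, 5]`), and then
#' z-scored (sample standard deviation). The fitted per-feature parameters
#' are returned so the identical transform can be re-applied to new data
#' with [apply_boxcox_zscore()].
#'
#' @param x numeric matrix or data.frame, pulses x features.
#' @return list with `x` (transformed matrix) and `params` (data.frame of
#'   per-feature `shift`, `lambda`, `mean`, `sd`).
#' @export
boxcox_zscore <- function(x) {
  x <- as.matrix(x)
  params <- data.frame(feature = colnames(x), shift = NA_real_,
                       lambda = NA_real_, mean = NA_real_, sd = NA_real_)
  out <- x
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    if (length(unique(v)) < 2L)
      stop_transform("feature '%s' is constant; Box-Cox undefined", colnames(x)[j])
    shift <- if (min(v) <= 0) -min(v) + 1e-6 else 0
    y <- v + shift
    lam <- boxcox_mle(y)
    z <- boxcox_apply(y, lam)
    m <- mean(z); s <- stats::sd(z)
    if (s == 0)
      stop_transform("feature '%s' is constant after transform", colnames(x)[j])
    out[, j] <- (z - m) / s
    params[j, c("shift", "lambda", "mean", "sd")] <- c(shift, lam, m, s)
  }
  list(x = out, params = params)
}

#' @rdname boxcox_zscore
#' @param params fitted parameter table from [boxcox_zscore()].
#' @export
apply_boxcox_zscore <- function(x, params) {
  x <- as.matrix(x)
  if (!identical(colnames(x), params$feature))
    stop_transform("feature columns do not match the fitted parameters")
  out <- x
  for (j in seq_len(ncol(x))) {
    y <- x[, j] + params$shift[j]
    if (any(y <= 0))
      y <- pmax(y, 1e-9)  # new data may undershoot the training shift
    z <- boxcox_apply(y, params$lambda[j])
    out[, j] <- (z - params$mean[j]) / params$sd[j]
  }
  out
}

boxcox_apply <- function(y, lambda) {
  if (abs(lambda) < 1e-12) log(y) else (y^lambda - 1) / lambda
}

# profile log-likelihood MLE for the Box-Cox exponent on strictly positive data
boxcox_mle <- function(y, interval = c(-5, 5)) {
  n <- length(y)
  slog <- sum(log(y))
  nll <- function(lam) {
    z <- boxcox_apply(y, lam)
    v <- pop_var(z)
    if (!is.finite(v) || v <= 0) return(Inf)
    n / 2 * log(v) - (lam - 1) * slog
  }
  stats::optimize(nll, interval = interval)$minimum
}

#' Fit regularized neighborhood component analysis weights
#'
#' Maximizes the regularized expected leave-one-out accuracy of a soft
#' nearest-neighbor rule: with per-feature weights `w`, the distance between
#' pulses i and j is the weighted Manhattan distance
#' `d_ij = sum_r w_r^2 |x_ir - x_jr|`, soft-neighbor probabilities are
#' `p_ij = exp(-d_ij) / sum_k exp(-d_ik)` (with `p_ii = 0`), and the objective
#' is `sum_i sum_{j: y_j = y_i} p_ij - lambda * sum_r w_r^2`. Optimization is
#' batch gradient ascent with an adaptive step (halved when the objective
#' would decrease), starting from `w_r = 1`; weights enter squared so the
#' returned `abs(w)` is effectively non-negative.
#'
#' @param x standardized feature matrix (pulses x features).
#' @param y binary labels (any two-level vector).
#' @param lambda regularization strength (>= 0).
#' @param max_iter maximum gradient iterations.
#' @param tol relative objective-change stopping tolerance.
#' @return object of class `nca_fit`: list with `weights` (named, >= 0),
#'   `lambda`, `objective` (trace over accepted iterations), `converged`.
#' @export
nca_fit <- function(x, y, lambda = 0, max_iter = 200, tol = 1e-6) {
  x <- as.matrix(x)
  y <- as.factor(y)
  n <- nrow(x); p <- ncol(x)
  if (min(table(y)) < 2L) stop_parameter("need at least 2 samples per class")
  same <- outer(as.integer(y), as.integer(y), "==") * 1
  diag(same) <- 0
  # per-feature pairwise absolute differences, cached (n kept moderate by
  # callers; 19 features x n^2 doubles)
  A <- lapply(seq_len(p), function(r) abs(outer(x[, r], x[, r], "-")))

  objective_and_grad <- function(w) {
    w2 <- w^2
    D <- matrix(0, n, n)
    for (r in seq_len(p)) D <- D + w2[r] * A[[r]]
    E <- exp(-D)
    diag(E) <- 0
    rs <- rowSums(E)
    rs[rs == 0] <- 1
    P <- E / rs
    p_match <- rowSums(P * same)
    obj <- sum(p_match) - lambda * sum(w2)
    grad <- numeric(p)
    PM <- P * same
    for (r in seq_len(p)) {
      grad[r] <- 2 * w[r] * (sum(p_match * rowSums(P * A[[r]])) -
                               sum(PM * A[[r]])) - 2 * lambda * w[r]
    }
    list(obj = obj, grad = grad)
  }

  w <- rep(1, p)
  og <- objective_and_grad(w)
  if (!is.finite(og$obj)) pq_error("ppgqc_optimization_error", "non-finite NCA objective")
  trace <- og$obj
  step <- 1 / n
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    accepted <- FALSE
    for (try in 1:30) {
      w_new <- w + step * og$grad
      og_new <- objective_and_grad(w_new)
      if (is.finite(og_new$obj) && og_new$obj >= og$obj) {
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) { converged <- TRUE; break }
    rel <- (og_new$obj - og$obj) / max(1e-12, abs(og$obj))
    w <- w_new; og <- og_new
    trace <- c(trace, og$obj)
    step <- step * 1.1
    if (rel < tol) { converged <- TRUE; break }
  }
  structure(list(weights = stats::setNames(abs(w), colnames(x)),
                 lambda = lambda, objective = trace, converged = converged),
            class = "nca_fit")
}

#' @export
print.nca_fit <- function(x, ...) {
  cat(sprintf("<nca_fit> lambda = %g, objective %.4f (%d iterations)\n",
              x$lambda, x$objective[length(x$objective)],
              length(x$objective) - 1L))
  print(round(sort(x$weights, decreasing = TRUE), 4))
  invisible(x)
}

#' Default regularization grid for NCA
#'
#' Log-spaced values in `[1e-4, 1]`, scaled by `1/n` to keep the penalty
#' commensurate with the summed objective.
#'
#' @param n number of training pulses.
#' @param length grid size.
#' @return numeric vector of lambda values.
#' @export
nca_lambda_grid <- function(n, length = 20) {
  exp(seq(log(1e-4), log(1), length.out = length)) / n
}

# stratified fold assignment: shuffles within each class, then deals folds
# round-robin so every training fold keeps both classes
stratified_folds <- function(y, folds) {
  f <- integer(length(y))
  for (lv in unique(y)) {
    idx <- sample(which(y == lv))
    f[idx] <- rep_len(seq_len(folds), length(idx))
  }
  f
}

#' Tune the NCA regularization parameter by cross-validation
#'
#' For each lambda in the grid, fits NCA on each training fold and scores the
#' held-out fold with a 1-nearest-neighbor rule in the fitted weighted
#' Manhattan metric; returns the lambda with the smallest mean
#' misclassification rate (ties go to the smallest lambda).
#'
#' @param x standardized feature matrix.
#' @param y binary labels.
#' @param grid candidate lambda values.
#' @param folds number of CV folds.
#' @param seed integer seed for the fold assignment.
#' @param max_iter passed to [nca_fit()].
#' @return list with `lambda`, `cv_loss`, and the per-grid `losses`.
#' @export
nca_tune_lambda <- function(x, y, grid = NULL, folds = 10, seed = 1,
                            max_iter = 100) {
  x <- as.matrix(x); y <- as.factor(y)
  if (is.null(grid)) grid <- nca_lambda_grid(nrow(x))
  if (!length(grid)) stop_parameter("empty lambda grid")
  set.seed(derive_seed(seed, 1L))
  fold_id <- stratified_folds(y, folds)
  losses <- vapply(grid, function(lam) {
    fold_loss <- vapply(seq_len(folds), function(k) {
      tr <- fold_id != k; te <- !tr
      if (!any(te) || min(table(y[tr])) < 2L) return(NA_real_)
      fit <- nca_fit(x[tr, , drop = FALSE], y[tr], lambda = lam,
                     max_iter = max_iter)
      pred <- knn_weighted(x[tr, , drop = FALSE], y[tr],
                           x[te, , drop = FALSE], k = 1L,
                           w = fit$weights^2, metric = "manhattan")
      mean(pred$label != y[te])
    }, numeric(1))
    mean(fold_loss, na.rm = TRUE)
  }, numeric(1))
  best <- which(losses == min(losses))[1L]  # ties -> smallest lambda
  list(lambda = grid[best], cv_loss = losses[best], losses = losses,
       grid = grid)
}

#' Stability selection over repeated NCA runs
#'
#' Runs NCA `runs` times, each on a random subsample of the training pulses
#' (the run-to-run variability source), marks features whose weight exceeds
#' `threshold_frac` of the run's maximum weight, and returns the features
#' marked in at least `ceil(stability_frac * runs)` runs.
#'
#' @param x standardized feature matrix.
#' @param y binary labels.
#' @param lambda regularization strength (typically from [nca_tune_lambda()]).
#' @param runs number of repeated fits.
#' @param threshold_frac weight threshold as a fraction of the max weight.
#' @param stability_frac minimum fraction of runs a feature must be marked in.
#' @param subsample fraction of pulses drawn (without replacement) per run.
#' @param seed integer seed.
#' @param max_iter passed to [nca_fit()].
#' @return object of class `nca_selection`: list with `stable_set`
#'   (character), `counts` (runs selected per feature), `weights` (runs x
#'   features matrix), `lambda`.
#' @export
nca_stable_select <- function(x, y, lambda, runs = 10, threshold_frac = 0.2,
                              stability_frac = 0.8, subsample = 0.9, seed = 1,
                              max_iter = 100) {
  x <- as.matrix(x); y <- as.factor(y)
  if (runs < 1L) stop_parameter("runs must be >= 1")
  p <- ncol(x)
  sel <- matrix(FALSE, nrow = runs, ncol = p,
                dimnames = list(NULL, colnames(x)))
  wts <- matrix(NA_real_, nrow = runs, ncol = p,
                dimnames = list(NULL, colnames(x)))
  for (r in seq_len(runs)) {
    set.seed(derive_seed(seed, r))
    repeat {
      idx <- sample(nrow(x), max(4L, round(subsample * nrow(x))))
      if (min(table(y[idx])) >= 2L) break
    }
    fit <- nca_fit(x[idx, , drop = FALSE], y[idx], lambda = lambda,
                   max_iter = max_iter)
    wts[r, ] <- fit$weights
    sel[r, ] <- fit$weights > threshold_frac * max(fit$weights)
  }
  counts <- colSums(sel)
  need <- ceiling(stability_frac * runs)
  stable <- colnames(x)[counts >= need]
  if (!length(stable))
    warning("stability selection returned an empty set; callers should fall back to the full feature set")
  structure(list(stable_set = stable, counts = counts, weights = wts,
                 lambda = lambda, runs = runs,
                 threshold_frac = threshold_frac,
                 stability_frac = stability_frac),
            class = "nca_selection")
}

#' @export
print.nca_selection <- function(x, ...) {
  cat(sprintf("<nca_selection> %d/%d runs required; stable set (%d): %s\n",
              ceiling(x$stability_frac * x$runs), x$runs,
              length(x$stable_set), paste(x$stable_set, collapse = ", ")))
  invisible(x)
}

# weighted k-nearest-neighbor prediction used by the NCA tuner and the kNN
# classifier family; w are per-feature distance weights
knn_weighted <- function(x_train, y_train, x_new, k = 1L, w = NULL,
                         metric = c("euclidean", "manhattan"),
                         vote = c("uniform", "distance")) {
  metric <- match.arg(metric)
  vote <- match.arg(vote)
  x_train <- as.matrix(x_train); x_new <- as.matrix(x_new)
  y_train <- as.factor(y_train)
  if (is.null(w)) w <- rep(1, ncol(x_train))
  pos_level <- levels(y_train)[nlevels(y_train)]
  score <- numeric(nrow(x_new))
  lab <- character(nrow(x_new))
  for (i in seq_len(nrow(x_new))) {
    d <- abs(sweep(x_train, 2L, x_new[i, ]))
    d <- if (metric == "manhattan") as.numeric(d %*% w)
         else sqrt(as.numeric((d^2) %*% w))
    nn <- order(d)[seq_len(min(k, length(d)))]
    wt <- if (vote == "uniform") rep(1, length(nn)) else 1 / pmax(d[nn], 1e-12)
    s <- sum(wt * (y_train[nn] == pos_level)) / sum(wt)
    score[i] <- s
    lab[i] <- if (s >= 0.5) pos_level else levels(y_train)[1L]
  }
  list(score = score, label = factor(lab, levels = levels(y_train)))
}
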