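test_that("Box-Cox conditioning standardizes and is reproducible", {
  set.seed(21)
  x <- cbind(lognorm = exp(rnorm(2000)),
             with_zeros = c(0, 0, rexp(1998)),
             gauss = rnorm(2000, 10, 2))
  bc <- boxcox_zscore(x)
  expect_lt(abs(bc$params$lambda[1]), 0.3)   # lognormal -> lambda near 0
  expect_equal(bc$params$shift[2], 1e-6)     # zeros shifted to positivity
  expect_equal(unname(colMeans(bc$x)), c(0, 0, 0), tolerance = 1e-6)
  expect_equal(unname(apply(bc$x, 2, sd)), c(1, 1, 1), tolerance = 1e-6)
  # stored parameters reproduce the transform exactly
  again <- apply_boxcox_zscore(x, bc$params)
  expect_equal(again, bc$x, tolerance = 1e-9)
  # lambda = 1 is affine: equals a plain z-score
  p1 <- data.frame(feature = "gauss", shift = 0,
                   lambda = 1, mean = mean(x[, 3] - 1), sd = sd(x[, 3]))
  z <- apply_boxcox_zscore(x[, 3, drop = FALSE], p1)
  expect_equal(as.numeric(z), as.numeric(scale(x[, 3])), tolerance = 1e-9)
  expect_error(boxcox_zscore(cbind(const = rep(2, 10), ok = 1:10)),
               class = "ppgqc_transform_error")
  err <- tryCatch(boxcox_zscore(cbind(bad_feat = rep(2, 10))),
                  ppgqc_transform_error = function(e) e)
  expect_match(conditionMessage(err), "bad_feat")
})

make_two_feature_problem <- function(n = 100, sd_noise = 1) {
  y <- rep(c("a", "b"), each = n / 2)
  x <- cbind(informative = ifelse(y == "a", -1, 1) + rnorm(n, 0, 0.3),
             noise = rnorm(n, 0, sd_noise))
  list(x = scale(x), y = factor(y))
}

test_that("NCA upweights informative features and shrinks under regularization", {
  set.seed(22)
  pb <- make_two_feature_problem()
  fit <- nca_fit(pb$x, pb$y, lambda = 0.01)
  expect_gt(fit$weights["informative"], 5 * fit$weights["noise"])
  # objective trace is non-decreasing
  expect_true(all(diff(fit$objective) >= -1e-9))
  # strong regularization shrinks everything
  fit0 <- nca_fit(pb$x, pb$y, lambda = 0)
  fit_big <- nca_fit(pb$x, pb$y, lambda = 50)
  expect_lt(max(fit_big$weights), 0.1 * max(fit0$weights))
  # 2-feature grid-search oracle: no grid point beats the fitted objective
  obj <- function(w) {
    d <- w[1]^2 * abs(outer(pb$x[, 1], pb$x[, 1], "-")) +
      w[2]^2 * abs(outer(pb$x[, 2], pb$x[, 2], "-"))
    E <- exp(-d); diag(E) <- 0
    P <- E / rowSums(E)
    same <- outer(as.integer(pb$y), as.integer(pb$y), "==") * 1; diag(same) <- 0
    sum(P * same) - 0.01 * sum(w^2)
  }
  grid <- expand.grid(w1 = seq(0, 4, by = 0.5), w2 = seq(0, 4, by = 0.5))
  best_grid <- max(apply(grid, 1, obj))
  expect_gte(obj(fit$weights) + 1e-6, best_grid)
})

test_that("duplicated informative features share weight symmetrically", {
  set.seed(23)
  pb <- make_two_feature_problem()
  x <- cbind(a = pb$x[, 1], b = pb$x[, 1], noise = pb$x[, 2])
  fit <- nca_fit(x, pb$y, lambda = 0.01)
  expect_lt(abs(fit$weights["a"] - fit$weights["b"]),
            0.2 * max(fit$weights[c("a", "b")]))
})

test_that("lambda tuning returns grid minima with sane degenerate behavior", {
  set.seed(24)
  pb <- make_two_feature_problem(n = 80)
  one <- nca_tune_lambda(pb$x, pb$y, grid = 0.05, folds = 4, seed = 1)
  expect_equal(one$lambda, 0.05)
  # well-separated classes: tiny CV loss
  tuned <- nca_tune_lambda(pb$x, pb$y, grid = c(0.001, 0.1), folds = 4, seed = 1)
  expect_lte(tuned$cv_loss, 0.05)
  # pure-noise labels: loss near the class-imbalance baseline
  yr <- factor(sample(rep(c("a", "b"), c(48, 32))))
  xr <- matrix(rnorm(80 * 3), 80)
  noise <- nca_tune_lambda(xr, yr, grid = 0.05, folds = 4, seed = 1)
  expect_lt(abs(noise$cv_loss - 0.4), 0.125)
})

test_that("stability selection vote behaves at the threshold extremes", {
  set.seed(25)
  pb <- make_two_feature_problem()
  sel0 <- nca_stable_select(pb$x, pb$y, lambda = 0.01, runs = 4,
                            threshold_frac = 0, seed = 2, max_iter = 40)
  expect_setequal(sel0$stable_set, colnames(pb$x))
  sel <- nca_stable_select(pb$x, pb$y, lambda = 0.01, runs = 4, seed = 2,
                           max_iter = 40)
  expect_true("informative" %in% sel$stable_set)
  # determinism under a fixed seed
  sel2 <- nca_stable_select(pb$x, pb$y, lambda = 0.01, runs = 4, seed = 2,
                            max_iter = 40)
  expect_identical(sel$weights, sel2$weights)
})
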