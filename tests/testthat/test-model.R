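## small synthetic full-rank design over the 14 feature names
make_design <- function(n, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * 14L), n, 14L, dimnames = list(NULL, feature_names()))
  as.data.frame(X)
}

test_that("OLS recovers coefficients exactly on noise-free data", {
  X <- make_design(200)
  beta <- seq(-0.5, 0.8, length.out = 14)
  y <- 0.3 + as.matrix(X) %*% beta
  fit <- fit_ols(X, drop(y))
  expect_equal(fit$intercept, 0.3, tolerance = 1e-9)
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-9)
  ## agrees with lm() as an independent route
  lmfit <- lm(y ~ ., data = cbind(y = drop(y), X))
  expect_equal(unname(coef(lmfit)),
               unname(c(fit$intercept, fit$coefficients)), tolerance = 1e-8)
})

test_that("orthogonal responses give near-zero slopes and mean intercept", {
  X <- make_design(4000, seed = 2)
  y <- rep(c(-1, 1), 2000) + 2
  fit <- fit_ols(X, y)
  expect_lt(max(abs(fit$coefficients)), 0.1)
  expect_equal(fit$intercept, 2, tolerance = 0.1)
})

test_that("duplicated feature columns warn and still fit finitely", {
  X <- make_design(100, seed = 3)
  X$second_best_ddG <- X$best_ddG
  y <- drop(as.matrix(X) %*% rep(0.1, 14)) + rnorm(100, 0, 0.01)
  expect_warning(fit <- fit_ols(X, y), "rank-deficient")
  expect_true(all(is.finite(fit$coefficients)))
  expect_true("second_best_ddG" %in% fit$aliased ||
                "best_ddG" %in% fit$aliased)
  ## the pseudoinverse fit still reproduces fitted values
  expect_equal(predict(fit, X), drop(cbind(1, as.matrix(X)) %*%
                                       c(fit$intercept, fit$coefficients)))
})

test_that("training rows filter by observed log2 fold change", {
  X <- make_design(3)
  obs <- c(-0.5, -0.05, 0.3)
  expect_equal(length(filter_training_rows(X, obs, -0.1)$observed), 1L)
  expect_equal(length(filter_training_rows(X, obs, 0)$observed), 2L)
  expect_error(filter_training_rows(X, obs, -1), "no training rows")
})

test_that("cross-validation detects signal and stays at null on noise", {
  X <- make_design(2000, seed = 4)
  X$gene_id <- sprintf("g%04d", seq_len(2000))
  beta <- seq(0.1, 0.4, length.out = 14)
  y <- drop(as.matrix(X[, feature_names()]) %*% beta) + rnorm(2000, 0, 1)
  cv <- cross_validate(X, y, k = 5, rng_seed = 31)
  expect_gt(mean(cv$cv$spearman_rho), 0.5)
  ## permuted responses: no fold correlation beyond noise
  set.seed(32)
  cv0 <- cross_validate(X, sample(y), k = 5, rng_seed = 31)
  expect_lt(abs(mean(cv0$cv$spearman_rho)), 0.05)
  ## folds are reproducible and split at the gene level
  cv2 <- cross_validate(X, y, k = 5, rng_seed = 31)
  expect_identical(cv$fold, cv2$fold)
  expect_error(cross_validate(X[1:3, ], y[1:3], k = 5), "k exceeds")
})

test_that("median-of-models prediction takes the row-wise median", {
  mk <- function(b0) structure(list(intercept = b0,
                                    coefficients = c(best_ddG = 0),
                                    n_train = 10L, rank = 2L),
                               class = "energy_lm")
  feats <- data.frame(best_ddG = c(1, 2))
  expect_equal(predict_median(list(mk(-1), mk(0), mk(2)), feats), c(0, 0))
  expect_equal(predict_median(list(mk(3), mk(3)), feats), c(3, 3))
  expect_equal(predict_median(list(mk(5)), feats), c(5, 5))
  bad <- mk(0); names(bad$coefficients) <- "sum_ddG"
  expect_error(predict_median(list(mk(0), bad), feats), "schema")
})

test_that("the fitted model object supports the classic method set", {
  X <- make_design(500, seed = 6)
  X$gene_id <- sprintf("g%03d", seq_len(500))
  X$mirna_id <- "m1"
  beta <- rep(c(0.2, -0.1), 7)
  y <- -0.5 + drop(as.matrix(X[, feature_names()]) %*% beta) +
    rnorm(500, 0, 0.3)
  fit <- energy_model(X, y, cutoff = 10, k = 5, rng_seed = 8)
  expect_s3_class(fit, "energy_model")
  expect_output(print(fit), "Spearman")
  expect_output(print(summary(fit)), "Per-fold")
  co <- coef(fit)
  expect_length(co, 15L)
  expect_equal(names(co)[1L], "(Intercept)")
  p <- predict(fit, X)
  expect_length(p, 500L)
  expect_equal(residuals(fit), y - predict(fit))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_equal(dim(sims), c(500L, 2L))
  ## training rows below the cutoff only
  fit2 <- energy_model(X, y, cutoff = -0.5, k = 3, rng_seed = 8)
  expect_equal(length(fit2$training$observed), sum(y <= -0.5))
})

test_that("model serialization round-trips predictions bit-identically", {
  X <- make_design(300, seed = 7)
  X$gene_id <- sprintf("g%03d", seq_len(300))
  y <- drop(as.matrix(X[, feature_names()]) %*% rep(0.15, 14)) +
    rnorm(300, 0, 0.2)
  fit <- energy_model(X, y, cutoff = 10, k = 4, rng_seed = 5)
  path <- tempfile(fileext = ".json")
  write_energy_model(fit, path)
  back <- read_energy_model(path)
  expect_identical(predict(back, X), predict(fit, X))
  expect_identical(back$feature_names, fit$feature_names)
  expect_equal(back$cv$spearman_rho, fit$cv$spearman_rho)
})

test_that("ranking is invariant to affine feature rescaling", {
  X <- make_design(200, seed = 9)
  y <- drop(as.matrix(X) %*% rep(0.2, 14)) + rnorm(200, 0, 0.1)
  fit <- fit_ols(X, y)
  ## rescale features; refit; predictions (hence ranking) are unchanged
  X2 <- as.data.frame(2 * as.matrix(X) + 5)
  fit2 <- fit_ols(X2, y)
  expect_equal(predict(fit2, X2), predict(fit, X), tolerance = 1e-8)
  expect_equal(unname(fit2$coefficients), unname(fit$coefficients) / 2,
               tolerance = 1e-8)
})
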