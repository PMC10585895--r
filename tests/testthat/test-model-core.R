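test_that("rmse and r_squared match hand arithmetic and handle errors", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2, 3), c(2, 2, 2)), sqrt(2 / 3))
  expect_error(rmse(1:3, 1:4), "equal length")

  expect_equal(r_squared(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(r_squared(c(1, 2, 3, 4), rep(2.5, 4)), 0)
  expect_equal(r_squared(c(1, 2, 3, 4), c(1, 2, 3, 5)), 0.8)
  expect_error(r_squared(rep(1, 4), rep(1, 4)), "constant")
})

test_that("ols recovers an exact linear signal and refuses rank deficiency", {
  d <- make_linear_data(40, 1, beta = 2, seed = 2)
  m <- fit_model(d$X, d$y, "ols")
  expect_equal(unname(m$coefficients["x1"]), 2, tolerance = 1e-10)
  expect_equal(m$intercept, 0, tolerance = 1e-10)
  expect_lt(m$cv_rmse, 1e-10)

  wide <- make_linear_data(10, 12, beta = 1, seed = 3)
  expect_error(fit_model(wide$X, wide$y, "ols"), "ridge")
})

test_that("lasso finds a noiseless signal among noise features", {
  d <- make_linear_data(60, 10, beta = 1, sigma = 0, seed = 4)
  m <- fit_model(d$X, d$y, "lasso", cv_config(fold_seed = 1))
  expect_true("x1" %in% selected_features(m))
  expect_lt(m$cv_rmse, 0.1)
  expect_gt(abs(m$coefficients["x1"]), 0.8)
  pred <- predict(m, d$X)
  expect_lt(rmse(d$y, pred), 0.1)
})

test_that("degenerate inputs fall back to intercept-only models", {
  y <- rep(3, 30)
  X <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("x1", "x2")))
  m <- fit_model(X, y, "lasso")
  expect_length(m$coefficients, 0)
  expect_equal(predict(m, X), rep(3, 30))

  expect_warning(m0 <- fit_model(X[, 0], y + rnorm(30), "ols"), "intercept-only")
  expect_length(m0$coefficients, 0)
})

test_that("intercept-only CV RMSE approximates sd(y)", {
  withr::with_seed(10, y <- rnorm(200, sd = 2))
  X <- matrix(rnorm(200), 200, 1, dimnames = list(NULL, "x1"))
  suppressWarnings(m <- fit_model(X[, 0, drop = FALSE], y, "ols"))
  expect_equal(m$cv_rmse, sd(y), tolerance = 0.15)
})

test_that("penalized fits are invariant to affine rescaling of a column", {
  d <- make_linear_data(80, 5, beta = c(1, -0.5), sigma = 0.2, seed = 6)
  cv <- cv_config(fold_seed = 42)
  m1 <- fit_model(d$X, d$y, "lasso", cv)
  X2 <- d$X
  X2[, 2] <- X2[, 2] * 10
  m2 <- fit_model(X2, d$y, "lasso", cv)
  # original-scale effect is preserved: beta2' = beta2 / 10
  expect_equal(unname(m2$coefficients["x2"] * 10),
               unname(m1$coefficients["x2"]), tolerance = 1e-6)
  expect_equal(predict(m1, d$X), predict(m2, X2), tolerance = 1e-6)
})

test_that("lasso sparsity is monotone along the path on a fixed fold split", {
  d <- make_linear_data(60, 8, beta = c(1, -1, 0.5), sigma = 0.3, seed = 7)
  fit <- glmnet::glmnet(d$X, d$y, alpha = 1)
  nz <- fit$df
  expect_true(all(diff(nz) >= 0))  # df grows as lambda decreases
})

test_that("adaptive ridge downweights the penalty on strong features", {
  d <- make_linear_data(100, 6, beta = c(2, 0, 0), sigma = 0.2, seed = 8)
  cv <- cv_config(fold_seed = 3)
  m <- fit_model(d$X, d$y, "adaptive_ridge", cv)
  expect_equal(unname(m$coefficients["x1"]), 2, tolerance = 0.2)
  mr <- fit_model(d$X, d$y, "ridge", cv)
  # adaptive weights shrink the signal coefficient less than plain ridge
  expect_gte(abs(m$coefficients["x1"]), abs(mr$coefficients["x1"]) - 1e-8)
})
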