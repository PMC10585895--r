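test_that("leave-one-out importance separates signal from noise", {
  d <- make_linear_data(80, 2, beta = 2, sigma = 0.3, seed = 31)
  imp <- loo_importance(d$X, d$y, B = 60, cv = cv_config(fold_seed = 1), seed = 2)
  expect_equal(imp$feature, c("x1", "x2"))
  expect_equal(dim(attr(imp, "r2")), c(60, 2))
  # removing the signal feature destabilizes the model far more
  expect_gt(imp$score[imp$feature == "x1"], imp$score[imp$feature == "x2"])
})

test_that("duplicated columns are symmetric and less important than real signal", {
  withr::with_seed(32, {
    x1 <- rnorm(100)
    x3 <- rnorm(100)
    X <- cbind(x1 = x1, x2 = x1, x3 = x3)
    y <- 2 * x3 + 0.1 * x1 + rnorm(100, sd = 0.2)
  })
  imp <- loo_importance(X, y, B = 60, cv = cv_config(fold_seed = 3), seed = 4)
  s <- setNames(imp$score, imp$feature)
  # removing either duplicate leaves the fit stable
  expect_gt(s["x3"], max(s["x1"], s["x2"]))
})

test_that("threshold search keeps the minimal sufficient set on noiseless data", {
  d <- make_linear_data(60, 3, beta = 1, sigma = 0, seed = 33)
  imp <- loo_importance(d$X, d$y, B = 40, cv = cv_config(fold_seed = 5), seed = 6)
  thr <- threshold_search(imp, d$X, d$y, technique = "ols", B_eval = 30, seed = 7)
  expect_equal(thr$q_best, "x1")
  expect_gt(thr$c_best, 0.99)
  # the tie-break chose the smaller of the equally-performing sets
  tied <- thr$trace[thr$trace$performance >= thr$c_best - 1e-6, ]
  expect_equal(min(tied$size), length(thr$q_best))
})

test_that("a single shared importance score returns the full set", {
  rec <- data.frame(feature = c("x1", "x2"), mean_r2 = c(0.5, 0.5),
                    sd_r2 = c(0.1, 0.1), score = c(0.2, 0.2))
  class(rec) <- c("aiwrap_importance", "data.frame")
  d <- make_linear_data(50, 2, beta = c(1, 1), sigma = 0.2, seed = 34)
  thr <- threshold_search(rec, d$X, d$y, B_eval = 20, seed = 8)
  expect_equal(sort(thr$q_best), c("x1", "x2"))
})

test_that("final model variants dispatch to OLS and ridge with guards", {
  d <- make_linear_data(50, 4, beta = c(1.5, -2), sigma = 0, seed = 35)
  m <- fit_final_model(d$X, d$y, c("x1", "x2"), "LLr", cv_config(fold_seed = 9))
  expect_equal(unname(m$coefficients[c("x1", "x2")]), c(1.5, -2),
               tolerance = 1e-8)
  expect_equal(m$technique, "ols")

  mr <- fit_final_model(d$X, d$y, c("x1", "x2"), "LR", cv_config(fold_seed = 9))
  expect_equal(mr$technique, "ridge")
  expect_equal(unname(mr$coefficients["x1"]), 1.5, tolerance = 0.2)

  expect_error(fit_final_model(d$X[1:3, ], d$y[1:3], paste0("x", 1:4), "LLr"),
               "LR")
  expect_warning(m0 <- fit_final_model(d$X, d$y, character(0), "LR"),
                 "intercept-only")
  expect_equal(predict(m0, d$X), rep(mean(d$y), 50))
})
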