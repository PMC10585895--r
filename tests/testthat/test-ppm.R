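test_that("random subset sampling respects the size law and k = 15 p default", {
  masks <- sample_random_subsets(50, 15 * 50, seed = 1)
  expect_equal(dim(masks), c(750, 50))
  expect_true(all(rowSums(masks) >= 1))

  # mean subset size under the uniform-size law is (p + 1) / 2
  big <- sample_random_subsets(50, 20000, seed = 2)
  expect_lt(abs(mean(rowSums(big)) - 25.5), 1)

  # reproducible by seed
  expect_identical(masks, sample_random_subsets(50, 750, seed = 1))
})

test_that("performance dataset rows carry oracle-consistent CV RMSE", {
  d <- make_linear_data(60, 12, beta = rep(1, 4), sigma = 0, seed = 3)
  masks <- rbind(c(rep(1L, 4), rep(0L, 8)),   # exactly the true features
                 c(rep(0L, 4), rep(1L, 8)))   # pure noise
  dp <- build_performance_dataset(d, masks, cv_config(fold_seed = 5))
  expect_equal(length(dp$c), 2)
  expect_equal(dp$provenance, c("initial", "initial"))
  expect_lt(dp$c[1], 0.1)                      # near-zero error on the oracle set
  expect_gt(dp$c[2], 0.8 * sd(d$y))            # null-model bound for pure noise
})

test_that("surrogate learns a monotone popcount signal", {
  p <- 12
  masks <- sample_random_subsets(p, 400, seed = 4)
  c_true <- rowSums(masks) / p
  dp <- aiwrap:::new_dperf(masks, c_true, rep("initial", 400))
  ppm <- train_ppm(dp, ppm_config(n_trees = 300), seed = 9)
  held <- sample_random_subsets(p, 100, seed = 5)
  pred <- predict_performance(ppm, held)
  expect_gt(cor(pred, rowSums(held) / p, method = "spearman"), 0.9)
})

test_that("constant performances give a constant predictor", {
  masks <- sample_random_subsets(6, 30, seed = 6)
  dp <- aiwrap:::new_dperf(masks, rep(0.7, 30), rep("initial", 30))
  ppm <- train_ppm(dp)
  expect_equal(predict_performance(ppm, masks[1:5, ]), rep(0.7, 5))
})

test_that("surrogate prediction performs zero base-model fits", {
  p <- 10
  d <- make_linear_data(50, p, beta = c(1, -1), sigma = 0.2, seed = 7)
  masks <- sample_random_subsets(p, 60, seed = 8)
  dp <- build_performance_dataset(d, masks, cv_config(fold_seed = 2))
  ppm <- train_ppm(dp, seed = 1)
  reset_fit_count()
  pred <- predict_performance(ppm, sample_random_subsets(p, 1000, seed = 9))
  expect_equal(fit_count(), 0L)
  expect_length(pred, 1000)
  expect_true(all(is.finite(pred)))
  # forest predictions stay within the training performance range
  expect_true(all(pred >= min(dp$c) - 1e-8 & pred <= max(dp$c) + 1e-8))

  expect_length(predict_performance(ppm, masks[0, , drop = FALSE]), 0)
  expect_error(predict_performance(ppm, matrix(1L, 1, p + 1)), "dimension")
})
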