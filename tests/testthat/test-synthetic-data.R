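test_that("covariance block has compound symmetry with the closed-form spectrum", {
  S <- build_covariance(50, 0.5)
  expect_equal(dim(S), c(50, 50))
  expect_equal(unname(diag(S)), rep(1, 50))
  expect_equal(S[1, 2], 0.5)
  expect_equal(S[2, 15], 0.5)
  expect_equal(S[1, 16], 0)
  expect_equal(S[20, 30], 0)
  expect_true(isSymmetric(S))

  # closed form for a full compound-symmetry block: 1 + (b-1) rho and 1 - rho
  S15 <- build_covariance(15, 0.5)
  ev <- sort(eigen(S15, symmetric = TRUE, only.values = TRUE)$values)
  expect_equal(ev, c(rep(0.5, 14), 8), tolerance = 1e-10)
  expect_true(all(eigen(S, only.values = TRUE)$values > 0))

  expect_equal(build_covariance(1, 0.9), matrix(1, 1, 1))
  expect_error(build_covariance(10, 1), "rho_block")
  expect_error(build_covariance(10, -0.1), "rho_block")
})

test_that("standard scenarios carry the study design parameters", {
  scns <- standard_scenarios()
  expect_named(scns, c("1_M", "2_M", "3_M", "4_M", "1_I", "2_I", "3_I"))
  s3m <- scns[["3_M"]]
  expect_equal(s3m$p, 100)
  expect_equal(s3m$n_train, 75)
  expect_equal(s3m$sigma, 0.25)
  s2i <- scns[["2_I"]]
  expect_equal(s2i$p, 25)
  expect_equal(sum(abs(s2i$beta_marginal) > 0), 10)
  expect_length(s2i$beta_interaction, 9)
  expect_equal(names(s2i$beta_interaction)[1], "x1:x2")
  for (s in scns) expect_equal(s$n_test, 500)
  # alternating +/-0.5 pattern on the ten target coefficients
  expect_equal(scns[["1_M"]]$beta_marginal[1:4], c(0.5, -0.5, 0.5, -0.5))
  expect_equal(sum(scns[["1_M"]]$beta_marginal != 0), 10)
})

test_that("simulate_dataset honors shapes, determinism and degenerate cases", {
  scn <- standard_scenarios()[["1_M"]]
  sim <- simulate_dataset(scn)
  expect_equal(dim(sim$train$X), c(50, 50))
  expect_equal(dim(sim$test$X), c(500, 50))
  expect_equal(colnames(sim$train$X)[c(1, 50)], c("x1", "x50"))
  expect_equal(sim$targets$marginal, paste0("x", 1:10))
  expect_false(anyNA(sim$train$X))

  # identical seeds give bit-identical draws; different seeds do not
  sim2 <- simulate_dataset(scn)
  expect_identical(sim$train, sim2$train)
  scn3 <- scn; scn3$seed <- 2L
  expect_false(identical(sim$train$y, simulate_dataset(scn3)$train$y))

  # noiseless null model: y is identically the intercept
  null_scn <- simulation_scenario("null", p = 3, n_train = 20, n_test = 10,
                                  sigma = 0, beta0 = 4, seed = 5)
  expect_equal(simulate_dataset(null_scn)$train$y, rep(4, 20))
})

test_that("generator recovers the target moments and the oracle error floor", {
  scn <- simulation_scenario("big", p = 20, n_train = 20000, n_test = 20000,
                             sigma = 0.25,
                             beta_marginal = c(rep(c(0.5, -0.5), 5), rep(0, 10)),
                             seed = 31)
  sim <- simulate_dataset(scn)
  X <- sim$train$X
  expect_lt(abs(mean(X[, 1])), 0.02)
  expect_lt(abs(stats::var(X[, 3]) - 1), 0.05)
  expect_lt(abs(stats::cor(X[, 1], X[, 2]) - 0.5), 0.02)
  expect_lt(abs(stats::cor(X[, 1], X[, 16])), 0.02)

  # predicting with the true coefficients leaves only the noise floor
  yhat <- drop(sim$test$X %*% scn$beta_marginal)
  expect_lt(abs(rmse(sim$test$y, yhat) - 0.25), 0.02)
})

test_that("interaction scenarios add the pairwise products to the outcome", {
  scn <- simulation_scenario(
    "int", p = 4, n_train = 50, n_test = 10, sigma = 0,
    beta_marginal = c(1, 0, 0, 0),
    beta_interaction = c("x1:x2" = 2, "x3:x4" = -1), seed = 7)
  sim <- simulate_dataset(scn)
  X <- sim$train$X
  expect_equal(sim$train$y,
               X[, 1] + 2 * X[, 1] * X[, 2] - X[, 3] * X[, 4])
  expect_equal(sim$targets$interaction, c("x1:x2", "x3:x4"))
  expect_error(simulation_scenario("bad", p = 3, n_train = 10,
                                   beta_marginal = numeric(3),
                                   beta_interaction = c("x3:x2" = 1)),
               "i < j")
})
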