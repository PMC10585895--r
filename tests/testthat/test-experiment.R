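test_that("selection F1 matches hand arithmetic", {
  targets <- paste0("x", 1:10)
  expect_equal(f1_selection(targets, targets), 1)
  expect_equal(f1_selection(c(targets, paste0("n", 1:5)), targets), 0.8)
  expect_equal(f1_selection(c("n1", "n2"), targets), 0)
  expect_equal(f1_selection(character(0), targets), 0)
  # interaction labels count like any feature
  expect_equal(f1_selection(c("x1:x2"), c("x1:x2", "x3")), 2 / 3)
})

# exhaustive pair-counting oracle with half credit for ties
auc_oracle <- function(freq, targets) {
  pos <- freq[names(freq) %in% targets]
  neg <- freq[!names(freq) %in% targets]
  total <- 0
  for (a in pos) for (b in neg) total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

test_that("selection AUC follows the rank formulation with tie credit", {
  f <- c(t1 = 10, t2 = 10, n1 = 10, n2 = 0)
  expect_equal(selection_auc(f, c("t1", "t2")), 0.75)
  expect_equal(selection_auc(f, c("t1", "t2")), auc_oracle(f, c("t1", "t2")))

  perfect <- c(t1 = 10, t2 = 9, n1 = 0, n2 = 0)
  expect_equal(selection_auc(perfect, c("t1", "t2")), 1)
  expect_equal(selection_auc(c(a = 3, b = 3, c = 3), "a"), 0.5)

  # label-independent frequencies give AUC near 1/2 (permutation check)
  withr::with_seed(51, {
    f2 <- setNames(rpois(400, 5), paste0("f", 1:400))
    targets <- paste0("f", sample(400, 200))
  })
  expect_equal(selection_auc(f2, targets), auc_oracle(f2, targets))
  expect_lt(abs(selection_auc(f2, targets) - 0.5), 0.1)
})

test_that("replicated experiments pool trials and degrade gracefully at n=1", {
  scn <- simulation_scenario("exp", p = 6, n_train = 50, n_test = 80,
                             sigma = 0.2, beta_marginal = c(1, -1, rep(0, 4)),
                             seed = 1)
  rep1 <- replicate_experiment(scn, methods = "lasso", n_trials = 1, seed = 3)
  expect_equal(nrow(rep1$trials), 1)
  expect_equal(rep1$summary$n_selected_min, rep1$summary$n_selected_max)

  rep3 <- replicate_experiment(scn, methods = "lasso", n_trials = 3, seed = 3)
  expect_equal(nrow(rep3$trials), 3)
  s <- rep3$summary
  expect_true(s$rmse_mean >= 0 && s$f1_embedded_mean >= 0 &&
                s$f1_embedded_mean <= 1)
  expect_true(s$n_selected_mean >= s$n_selected_min &&
                s$n_selected_mean <= s$n_selected_max)
  expect_true(s$rmse_ci_lo <= s$rmse_mean && s$rmse_mean <= s$rmse_ci_hi)
  # frequencies cover every candidate label and stay within trial count
  expect_true(all(rep3$frequencies$lasso <= 3))
  expect_named(rep3$auc, "lasso")
  expect_gte(rep3$auc[["lasso"]], 0)
  expect_lte(rep3$auc[["lasso"]], 1)
})
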