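# Small in-code fixtures shared across the suite.

# independent-feature dataset with linear signal on the first coefficients
make_linear_data <- function(n, p, beta, sigma = 0, seed = 1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("x", seq_len(p))
    y <- drop(X %*% c(beta, rep(0, p - length(beta)))) + rnorm(n, sd = sigma)
  })
  as_dataset(X, y)
}

# tiny GA budget used wherever search quality is not the point
tiny_ga <- function(pop = 8, generations = 4) {
  ga_config(pop = pop, generations = generations)
}

# exhaustive subset oracle: the support minimizing shared-fold CV RMSE of an
# OLS fit, ties broken toward the smaller subset
exhaustive_best_support <- function(train, fold_seed = 99) {
  p <- ncol(train$X)
  cv <- cv_config(fold_seed = fold_seed)
  best <- NULL
  best_c <- Inf
  for (code in seq_len(2^p - 1)) {
    mask <- as.integer(intToBits(code))[seq_len(p)]
    cols <- which(mask == 1)
    cvr <- fit_model(train$X[, cols, drop = FALSE], train$y, "ols", cv)$cv_rmse
    better <- cvr < best_c - 1e-9 ||
      (abs(cvr - best_c) <= 1e-9 && length(cols) < length(best))
    if (better) {
      best_c <- cvr
      best <- cols
    }
  }
  colnames(train$X)[best]
}
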