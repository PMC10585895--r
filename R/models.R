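# Base learners shared by every stage: OLS, LASSO, ridge and adaptive ridge
# with seeded 10-fold cross-validation, plus the RMSE / R-squared metrics.

#' Cross-validation configuration
#'
#' @param n_folds number of folds (default 10).
#' @param fold_seed optional seed fixing the fold assignment; when given, the
#'   same folds are reused across techniques so comparisons share splits.
#' @param lambda optional user lambda grid passed to glmnet (default: the
#'   standard 100-value log-spaced path auto-scaled from the data).
#' @return a list of class `aiwrap_cv`.
#' @export
cv_config <- function(n_folds = 10, fold_seed = NULL, lambda = NULL) {
  stopifnot(n_folds >= 2)
  structure(list(n_folds = as.integer(n_folds), fold_seed = fold_seed,
                 lambda = lambda), class = "aiwrap_cv")
}

#' Root mean square error
#'
#' @param y,yhat numeric vectors of equal length.
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  sqrt(mean((y - yhat)^2))
}

#' Coefficient of determination
#'
#' @param y observed outcome (must not be constant).
#' @param yhat predictions.
#' @return `1 - SS_res / SS_tot`; can be negative for models worse than the
#'   mean.
#' @export
r_squared <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("y and yhat must have equal length")
  if (length(y) < 2 || stats::var(y) == 0) {
    stop("r_squared is undefined for a constant outcome")
  }
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

new_model <- function(technique, intercept, coefficients, cv_rmse,
                      hyper = list()) {
  structure(list(technique = technique, intercept = intercept,
                 coefficients = coefficients, cv_rmse = cv_rmse,
                 hyperparameters = hyper),
            class = "aiwrap_model")
}

intercept_only_model <- function(y, foldid, technique = "ols") {
  mu <- mean(y)
  cvr <- cv_rmse_fixed(y, foldid, function(tr) {
    m <- mean(y[tr]); function(idx) rep(m, length(idx))
  })
  new_model(technique, mu, stats::setNames(numeric(0), character(0)), cvr)
}

# generic fold loop: fitter(train_idx) returns predictor(test_idx) -> yhat
cv_rmse_fixed <- function(y, foldid, fitter) {
  pred <- numeric(length(y))
  for (f in sort(unique(foldid))) {
    te <- which(foldid == f)
    predict_f <- fitter(which(foldid != f))
    pred[te] <- predict_f(te)
  }
  rmse(y, pred)
}

fit_ols <- function(X, y, foldid) {
  df <- data.frame(y = y, X, check.names = FALSE)
  fml <- stats::as.formula(paste("y ~", paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- stats::lm(fml, data = df)
  cvr <- cv_rmse_fixed(y, foldid, function(tr) {
    m <- stats::lm(fml, data = df[tr, , drop = FALSE])
    function(idx) unname(stats::predict(m, newdata = df[idx, , drop = FALSE]))
  })
  co <- stats::coef(fit)
  co[is.na(co)] <- 0
  new_model("ols", unname(co[1]), stats::setNames(unname(co[-1]), colnames(X)), cvr)
}

#' Fit a base regression model with cross-validated tuning
#'
#' The shared model-building primitive. Penalized techniques (`lasso`,
#' `ridge`, `adaptive_ridge`) tune the penalty strength by `n_folds`-fold
#' cross-validated mean squared error over the standard glmnet path; features
#' are standardized internally and coefficients are reported on the original
#' scale. `adaptive_ridge` weights the ridge penalty per feature by
#' `1 / (|beta_ridge| + 1e-6)` from a preliminary CV ridge fit. `ols` fits
#' unpenalized least squares and refuses rank-deficient problems
#' (`q >= n`). Degenerate inputs (no columns, constant outcome) yield an
#' intercept-only model with a warning where appropriate.
#'
#' Every call increments the audit counter reported by [fit_count()].
#'
#' @param X numeric matrix (n x q) of predictors; column names are the
#'   feature labels.
#' @param y numeric outcome of length n.
#' @param technique one of `"lasso"`, `"ridge"`, `"ols"`, `"adaptive_ridge"`.
#' @param cv a [cv_config()].
#' @return an object of class `aiwrap_model` with elements `technique`,
#'   `intercept`, `coefficients` (named, original scale), `cv_rmse` (the
#'   cross-validated RMSE at the chosen penalty) and `hyperparameters`.
#' @export
fit_model <- function(X, y, technique = c("lasso", "ridge", "ols", "adaptive_ridge"),
                      cv = cv_config()) {
  technique <- match.arg(technique)
  bump_fit_count()
  X <- as.matrix(X)
  if (ncol(X) > 0 && is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  stopifnot(nrow(X) == n || ncol(X) == 0, !anyNA(X), !anyNA(y))
  if (n < cv$n_folds) stop("need at least n_folds observations")
  foldid <- make_folds(n, cv$n_folds, cv$fold_seed)
  q <- ncol(X)
  if (q == 0) {
    warning("no features supplied; returning intercept-only model")
    return(intercept_only_model(y, foldid, technique))
  }
  if (stats::var(y) == 0) {
    return(intercept_only_model(y, foldid, technique))
  }
  if (technique == "ols") {
    if (q >= n) stop("ols is rank-deficient for q >= n; use ridge instead")
    return(fit_ols(X, y, foldid))
  }
  if (q == 1) {
    # glmnet needs >= 2 columns; for a single standardized feature the CV-tuned
    # penalty question is vacuous at this stage, so fall back to least squares
    m <- fit_ols(X, y, foldid)
    m$technique <- technique
    return(m)
  }
  alpha <- if (technique == "lasso") 1 else 0
  pf <- rep(1, q)
  if (technique == "adaptive_ridge") {
    pre <- glmnet::cv.glmnet(X, y, alpha = 0, foldid = foldid,
                             lambda = cv$lambda)
    b <- as.numeric(stats::coef(pre, s = "lambda.min"))[-1]
    pf <- 1 / (abs(b) + 1e-6)
    pf <- pf / mean(pf)
  }
  cvfit <- glmnet::cv.glmnet(X, y, alpha = alpha, foldid = foldid,
                             penalty.factor = pf, lambda = cv$lambda)
  i <- match(cvfit$lambda.min, cvfit$lambda)
  co <- as.numeric(stats::coef(cvfit, s = "lambda.min"))
  new_model(technique, co[1], stats::setNames(co[-1], colnames(X)),
            sqrt(cvfit$cvm[i]), hyper = list(lambda = cvfit$lambda.min))
}

#' Predict from a fitted base model
#'
#' @param object an `aiwrap_model`.
#' @param newdata matrix or data frame containing (at least) the model's
#'   feature columns.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.aiwrap_model <- function(object, newdata, ...) {
  nd <- as.matrix(newdata)
  feats <- names(object$coefficients)
  if (length(feats) == 0) {
    return(rep(object$intercept, nrow(nd)))
  }
  missing <- setdiff(feats, colnames(nd))
  if (length(missing)) stop("newdata lacks columns: ", paste(missing, collapse = ", "))
  drop(object$intercept + nd[, feats, drop = FALSE] %*% object$coefficients)
}

#' @export
print.aiwrap_model <- function(x, ...) {
  cat(sprintf("<aiwrap_model %s> %d features, %d selected, CV RMSE %.4g\n",
              x$technique, length(x$coefficients),
              length(selected_features(x)), x$cv_rmse))
  invisible(x)
}

#' Features with nonzero coefficients
#'
#' @param model an `aiwrap_model`.
#' @param tol absolute coefficient threshold defining "selected".
#' @return character vector of selected feature labels.
#' @export
selected_features <- function(model, tol = 1e-8) {
  names(model$coefficients)[abs(model$coefficients) > tol]
}
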