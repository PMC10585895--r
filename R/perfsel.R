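# Performance-based final filter: leave-one-feature-out bootstrap ridge
# models scored by out-of-bag R-squared give a coefficient-of-variation
# importance per feature; a genetic algorithm then searches the (finite)
# cutoff space for the threshold giving the best performance with the
# smallest feature set.

# single ridge fit at a fixed lambda (path anchored so lambda is on it);
# one-column designs fall back to least squares
ridge_at_lambda <- function(X, y, lambda) {
  if (ncol(X) == 1) {
    b <- stats::cov(X[, 1], y) / stats::var(X[, 1])
    a <- mean(y) - b * mean(X[, 1])
    list(predict = function(nd) a + b * nd[, 1])
  } else {
    fit <- glmnet::glmnet(X, y, alpha = 0, lambda = lambda * c(8, 4, 2, 1))
    list(predict = function(nd) drop(stats::predict(fit, nd, s = lambda)))
  }
}

oob_bootstrap <- function(n) {
  repeat {
    idx <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), idx)
    if (length(oob) >= 2) return(list(inbag = idx, oob = oob))
  }
}

#' Leave-one-feature-out bootstrap importance
#'
#' For each feature `l` of the design, fits `B` bootstrap ridge models on the
#' remaining columns and scores each on its out-of-bag rows by R-squared.
#' The importance of `l` is the coefficient of variation (sd/mean) of those
#' `B` values: a large CV means the model destabilizes when `l` is absent,
#' marking `l` as important. A non-positive mean OOB R-squared is treated as
#' catastrophic removal (score `Inf`).
#'
#' The ridge penalty is chosen once by 10-fold CV on the full design and
#' reused across all bootstrap refits.
#'
#' @param X design matrix restricted to the `q_embed` columns (>= 2 columns).
#' @param y outcome vector.
#' @param B number of bootstrap resamples (>= 2).
#' @param cv a [cv_config()] for the penalty choice.
#' @param seed optional seed.
#' @return data frame of class `aiwrap_importance` with columns `feature`,
#'   `mean_r2`, `sd_r2`, `score`, plus attribute `r2` (the B x q matrix of
#'   OOB values).
#' @export
loo_importance <- function(X, y, B = 100, cv = cv_config(), seed = NULL) {
  stopifnot(ncol(X) >= 2, B >= 2, stats::var(y) > 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- nrow(X)
  q <- ncol(X)
  foldid <- make_folds(n, min(cv$n_folds, n), cv$fold_seed)
  lambda <- glmnet::cv.glmnet(X, y, alpha = 0, foldid = foldid)$lambda.min
  boots <- lapply(seq_len(B), function(b) oob_bootstrap(n))
  r2 <- matrix(NA_real_, nrow = B, ncol = q, dimnames = list(NULL, colnames(X)))
  for (l in seq_len(q)) {
    Xl <- X[, -l, drop = FALSE]
    for (b in seq_len(B)) {
      bi <- boots[[b]]
      yoob <- y[bi$oob]
      if (stats::var(yoob) == 0) {
        r2[b, l] <- NA_real_
        next
      }
      fit <- ridge_at_lambda(Xl[bi$inbag, , drop = FALSE], y[bi$inbag], lambda)
      r2[b, l] <- r_squared(yoob, fit$predict(Xl[bi$oob, , drop = FALSE]))
    }
  }
  mu <- colMeans(r2, na.rm = TRUE)
  sdv <- apply(r2, 2, stats::sd, na.rm = TRUE)
  score <- ifelse(mu > 0, sdv / mu, Inf)
  out <- data.frame(feature = colnames(X), mean_r2 = mu, sd_r2 = sdv,
                    score = score, row.names = NULL)
  attr(out, "r2") <- r2
  class(out) <- c("aiwrap_importance", "data.frame")
  out
}

# mean bootstrap OOB R^2 of the model on the kept columns; shared resamples
# across candidate sets keep cutoff comparisons fair
evaluate_feature_set <- function(X, y, keep, technique, boots, cv) {
  Xk <- X[, keep, drop = FALSE]
  n <- nrow(X)
  use_ols <- technique == "ols" && length(keep) < n - 1
  lambda <- NULL
  if (!use_ols) {
    if (ncol(Xk) >= 2) {
      foldid <- make_folds(n, min(cv$n_folds, n), cv$fold_seed)
      lambda <- glmnet::cv.glmnet(Xk, y, alpha = 0, foldid = foldid)$lambda.min
    }
  }
  vals <- vapply(boots, function(bi) {
    yoob <- y[bi$oob]
    if (stats::var(yoob) == 0) return(NA_real_)
    pred <- tryCatch({
      if (use_ols) {
        df <- data.frame(y = y[bi$inbag], Xk[bi$inbag, , drop = FALSE], check.names = FALSE)
        fml <- stats::as.formula(paste("y ~", paste(sprintf("`%s`", colnames(Xk)), collapse = " + ")))
        m <- stats::lm(fml, data = df)
        co <- stats::coef(m); co[is.na(co)] <- 0
        drop(co[1] + Xk[bi$oob, , drop = FALSE] %*% co[-1])
      } else {
        fit <- ridge_at_lambda(Xk[bi$inbag, , drop = FALSE], y[bi$inbag],
                               lambda %||% 0.01)
        fit$predict(Xk[bi$oob, , drop = FALSE])
      }
    }, error = function(e) rep(mean(y[bi$inbag]), length(bi$oob)))
    r_squared(yoob, pred)
  }, numeric(1))
  mean(vals, na.rm = TRUE)
}

#' Dynamic-cutoff search over importance scores
#'
#' The candidate cutoffs are the midpoints between consecutive distinct
#' sorted (finite) scores, plus the keep-everything cutoff; features with
#' score at or above the cutoff are kept (infinite scores are always kept).
#' A genetic algorithm with a real-valued gene mapped onto this finite grid
#' searches for the cutoff whose kept set gives the best mean bootstrap
#' out-of-bag R-squared; cutoffs tied within `tie_tol` are broken toward the
#' smaller feature set. The empty set is never a candidate.
#'
#' @param records an `aiwrap_importance` table from [loo_importance()].
#' @param X,y the design (columns matching `records$feature`) and outcome.
#' @param ga a [ga_config()] (population/generations reused for the cutoff
#'   GA).
#' @param technique `"ols"` (used when the kept set is small enough, ridge
#'   otherwise) or `"ridge"`.
#' @param B_eval bootstrap resamples per cutoff evaluation.
#' @param tie_tol performance tie tolerance.
#' @param seed optional seed.
#' @return list of class `aiwrap_threshold`: `c_cutoff`, `q_best` (kept
#'   labels), `c_best` (mean OOB R-squared), `technique`, and the evaluated
#'   `trace` (data frame of cutoff, performance, set size).
#' @export
threshold_search <- function(records, X, y, ga = ga_config(pop = 16, generations = 8),
                             technique = c("ridge", "ols"), B_eval = 50,
                             tie_tol = 1e-6, seed = NULL) {
  stopifnot(inherits(records, "aiwrap_importance"), nrow(records) >= 1)
  technique <- match.arg(technique)
  if (!is.null(seed)) set.seed(as.integer(seed))
  scores <- stats::setNames(records$score, records$feature)
  finite <- sort(unique(scores[is.finite(scores)]))
  if (length(finite) <= 1) {
    # all features share one score: only the full set is admissible
    keep <- records$feature
    boots <- lapply(seq_len(B_eval), function(b) oob_bootstrap(nrow(X)))
    cb <- evaluate_feature_set(X, y, keep, technique, boots, cv_config())
    return(structure(list(c_cutoff = min(scores), q_best = keep, c_best = cb,
                          technique = technique,
                          trace = data.frame(cutoff = min(scores), performance = cb,
                                             size = length(keep))),
                     class = "aiwrap_threshold"))
  }
  grid <- c(finite[1], (finite[-length(finite)] + finite[-1]) / 2)
  if (any(!is.finite(scores))) {
    # infinite scores mark catastrophic removals: offer the cutoff that keeps
    # only those always-kept features
    grid <- c(grid, finite[length(finite)] + 1)
  }
  boots <- lapply(seq_len(B_eval), function(b) oob_bootstrap(nrow(X)))
  cv <- cv_config()

  evaluated <- new.env(parent = emptyenv())
  eval_cutoff <- function(g_idx) {
    key <- as.character(g_idx)
    hit <- evaluated[[key]]
    if (!is.null(hit)) return(hit)
    cutoff <- grid[g_idx]
    keep <- records$feature[scores >= cutoff | !is.finite(scores)]
    perf <- evaluate_feature_set(X, y, keep, technique, boots, cv)
    rec <- list(cutoff = cutoff, keep = keep, performance = perf)
    evaluated[[key]] <- rec
    rec
  }

  # real-valued-gene GA over the finite grid (exhaustive when the grid is
  # small enough to enumerate within the GA budget)
  n_grid <- length(grid)
  budget <- ga$pop * ga$generations
  if (n_grid <= budget) {
    for (g_idx in seq_len(n_grid)) eval_cutoff(g_idx)
  } else {
    genes <- stats::runif(ga$pop)
    to_idx <- function(g) pmin(n_grid, pmax(1L, as.integer(round(g * (n_grid - 1))) + 1L))
    for (gen in seq_len(ga$generations)) {
      perfs <- vapply(to_idx(genes), function(i) eval_cutoff(i)$performance, numeric(1))
      fitness <- -perfs
      nxt <- numeric(ga$pop)
      nxt[1] <- genes[which.min(fitness)]
      for (i in 2:ga$pop) {
        pa <- genes[tournament_pick(fitness, ga$tournament)]
        pb <- genes[tournament_pick(fitness, ga$tournament)]
        child <- if (stats::runif(1) < ga$p_crossover) (pa + pb) / 2 else pa
        child <- child + stats::rnorm(1, sd = 0.1)
        nxt[i] <- min(1, max(0, child))
      }
      genes <- nxt
    }
  }

  recs <- mget(ls(evaluated), envir = evaluated)
  perfs <- vapply(recs, `[[`, numeric(1), "performance")
  sizes <- vapply(recs, function(r) length(r$keep), numeric(1))
  cutoffs <- vapply(recs, `[[`, numeric(1), "cutoff")
  best_perf <- max(perfs)
  tied <- which(perfs >= best_perf - tie_tol)
  winner <- tied[order(sizes[tied], -cutoffs[tied])][1]
  structure(list(
    c_cutoff = cutoffs[[winner]],
    q_best = recs[[winner]]$keep,
    c_best = perfs[[winner]],
    technique = technique,
    trace = data.frame(cutoff = cutoffs, performance = perfs, size = sizes,
                       row.names = NULL)),
    class = "aiwrap_threshold")
}

#' Fit the final predictive model on the selected features
#'
#' `LLr` fits non-penalized least squares (only admissible when the set is
#' smaller than the sample size); `LR` fits 10-fold CV ridge. An empty set
#' under `LR` yields the intercept-only model.
#'
#' @param X full design matrix containing the `q_best` columns.
#' @param y outcome.
#' @param q_best character vector of final feature labels.
#' @param variant `"LLr"` or `"LR"`.
#' @param cv a [cv_config()].
#' @return an `aiwrap_model`.
#' @export
fit_final_model <- function(X, y, q_best, variant = c("LLr", "LR"),
                            cv = cv_config()) {
  variant <- match.arg(variant)
  if (variant == "LLr") {
    if (length(q_best) == 0) stop("LLr needs a nonempty feature set")
    if (length(q_best) >= length(y)) {
      stop("LLr (non-penalized) needs |q_best| < n; use the LR variant")
    }
    fit_model(X[, q_best, drop = FALSE], y, "ols", cv)
  } else {
    fit_model(X[, q_best, drop = FALSE], y, "ridge", cv)
  }
}
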