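# Performance Prediction Model: random feature subsets are scored by real
# cross-validated fits to build D_perf, and a random-forest regressor learns
# the subset-membership -> performance map so later candidates can be scored
# without model building.

#' PPM configuration
#'
#' @param k_multiplier size of the initial random-subset sample as a multiple
#'   of `p` (default 15, so `k = 15 * p`).
#' @param n_trees random-forest size.
#' @param size_law how subset sizes are drawn in [sample_random_subsets()]:
#'   `"uniform_size"` (size uniform on `1..p`, then a uniform subset of that
#'   size) or `"bernoulli"` (each feature kept with probability 1/2, empty
#'   masks repaired).
#' @return list of class `aiwrap_ppm_config`.
#' @export
ppm_config <- function(k_multiplier = 15, n_trees = 500,
                       size_law = c("uniform_size", "bernoulli")) {
  stopifnot(k_multiplier >= 1)
  structure(list(k_multiplier = as.integer(k_multiplier),
                 n_trees = as.integer(n_trees),
                 size_law = match.arg(size_law)),
            class = "aiwrap_ppm_config")
}

#' Sample random feature subsets
#'
#' Draws `k` nonempty binary membership masks over `p` features. Under the
#' default size law the subset size is uniform on `{1, ..., p}` and the
#' members are then drawn uniformly without replacement, covering the whole
#' size spectrum.
#'
#' @param p number of features.
#' @param k number of masks.
#' @param seed optional seed (otherwise the current RNG stream is used).
#' @param size_law see [ppm_config()].
#' @return a `k x p` binary matrix, one mask per row.
#' @export
sample_random_subsets <- function(p, k, seed = NULL,
                                  size_law = c("uniform_size", "bernoulli")) {
  stopifnot(p >= 1, k >= 1)
  size_law <- match.arg(size_law)
  draw <- function() {
    masks <- matrix(0L, nrow = k, ncol = p)
    for (j in seq_len(k)) {
      if (size_law == "uniform_size") {
        s <- sample.int(p, 1)
        masks[j, sample.int(p, s)] <- 1L
      } else {
        m <- stats::rbinom(p, 1, 0.5)
        if (sum(m) == 0) m[sample.int(p, 1)] <- 1L
        masks[j, ] <- m
      }
    }
    masks
  }
  if (is.null(seed)) draw() else withr::with_seed(as.integer(seed), draw())
}

new_dperf <- function(masks, c_values, provenance) {
  structure(list(masks = masks, c = as.numeric(c_values),
                 provenance = provenance),
            class = "aiwrap_dperf")
}

#' @export
print.aiwrap_dperf <- function(x, ...) {
  cat(sprintf("<aiwrap_dperf> %d subsets x %d features, c in [%.4g, %.4g]\n",
              nrow(x$masks), ncol(x$masks), min(x$c), max(x$c)))
  invisible(x)
}

dperf_add <- function(dperf, mask, c_value, provenance = "wrapper") {
  new_dperf(rbind(dperf$masks, as.integer(mask)),
            c(dperf$c, c_value),
            c(dperf$provenance, provenance))
}

# real fit of one masked subset; the subset's performance c is its seeded
# 10-fold CV RMSE. A failed fit falls back to the null-model bound sd(y).
eval_subset <- function(train, mask, cv) {
  cols <- which(mask > 0)
  tryCatch(
    fit_model(train$X[, cols, drop = FALSE], train$y, "lasso", cv)$cv_rmse,
    error = function(e) {
      warning("base-model fit failed (", conditionMessage(e),
              "); recording c = sd(y)")
      stats::sd(train$y)
    })
}

#' Build the performance dataset D_perf
#'
#' Fits one real LASSO model per subset (on the masked columns of the
#' training data) and records its cross-validated RMSE as the subset's
#' performance `c`. This table is the surrogate's training data and grows
#' during the wrapper search.
#'
#' @param train an `aiwrap_dataset`.
#' @param subsets binary mask matrix from [sample_random_subsets()].
#' @param cv a [cv_config()].
#' @return an object of class `aiwrap_dperf` with elements `masks`, `c`, and
#'   a per-row `provenance` flag (`"initial"` here; the wrapper appends
#'   `"wrapper"` rows).
#' @export
build_performance_dataset <- function(train, subsets, cv = cv_config()) {
  stopifnot(inherits(train, "aiwrap_dataset"), nrow(subsets) >= 1,
            ncol(subsets) == ncol(train$X))
  c_values <- vapply(seq_len(nrow(subsets)),
                     function(j) eval_subset(train, subsets[j, ], cv),
                     numeric(1))
  new_dperf(subsets, c_values, rep("initial", nrow(subsets)))
}

#' Train the performance prediction model
#'
#' Fits a random-forest regression of performance `c` on the binary
#' membership columns of `D_perf`. Duplicate masks are deduplicated (first
#' recorded performance kept) before training. Retraining on an extended
#' `D_perf` replaces the forest (stateless retrain).
#'
#' @param dperf an `aiwrap_dperf`.
#' @param config a [ppm_config()].
#' @param seed optional seed for the forest's resampling.
#' @return object of class `aiwrap_ppm`.
#' @export
train_ppm <- function(dperf, config = ppm_config(), seed = NULL) {
  stopifnot(inherits(dperf, "aiwrap_dperf"), length(dperf$c) >= 10)
  keys <- apply(dperf$masks, 1, paste, collapse = "")
  keep <- !duplicated(keys)
  x <- dperf$masks[keep, , drop = FALSE]
  yv <- dperf$c[keep]
  p <- ncol(x)
  colnames(x) <- paste0("x", seq_len(p))
  fit <- function() {
    if (stats::var(yv) == 0) {
      # degenerate surrogate: constant predictor
      list(constant = yv[1])
    } else {
      # tiny subset spaces legitimately yield few distinct performances;
      # silence the forest's advisory about near-discrete responses
      withCallingHandlers(
        randomForest::randomForest(x, yv, ntree = config$n_trees,
                                   mtry = max(1L, floor(p / 3))),
        warning = function(w) {
          if (grepl("five or fewer unique values", conditionMessage(w))) {
            invokeRestart("muffleWarning")
          }
        })
    }
  }
  forest <- if (is.null(seed)) fit() else withr::with_seed(as.integer(seed), fit())
  structure(list(forest = forest, p = p, n_train = nrow(x)),
            class = "aiwrap_ppm")
}

#' Predict subset performance with the surrogate
#'
#' Scores candidate masks through the trained forest; no model fitting
#' occurs ([fit_count()] is untouched).
#'
#' @param ppm an `aiwrap_ppm`.
#' @param subsets binary mask matrix with `p` columns (may have zero rows).
#' @return numeric vector of predicted performances `C_pred`.
#' @export
predict_performance <- function(ppm, subsets) {
  stopifnot(inherits(ppm, "aiwrap_ppm"))
  subsets <- rbind(subsets)
  if (nrow(subsets) == 0) return(numeric(0))
  if (ncol(subsets) != ppm$p) stop("mask dimension does not match the PPM")
  if (!is.null(ppm$forest$constant)) return(rep(ppm$forest$constant, nrow(subsets)))
  colnames(subsets) <- paste0("x", seq_len(ppm$p))
  unname(stats::predict(ppm$forest, subsets))
}
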