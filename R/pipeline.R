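# Orchestration of the four stages into the published variants:
#   AIWrap-L   = PPM -> GA wrapper -> embedded LASSO (final model = embedded)
#   AIWrap-LLr = ... -> performance filter, final OLS
#   AIWrap-LR  = ... -> performance filter, final ridge
#   StW        = GA wrapper with all-real fits -> embedded LASSO

#' Run the AIWrap pipeline on a training dataset
#'
#' Executes PPM construction (random subsets scored by real fits, forest
#' surrogate), the surrogate-assisted GA wrapper search, embedded LASSO
#' selection over the two-way interaction expansion of `q_wrap`, and — for
#' the `LLr`/`LR` variants — the bootstrap-importance performance filter.
#' One master seed deterministically derives every stage seed, so two runs
#' with the same seed produce identical results. Selection never sees test
#' data: evaluation is the caller's concern.
#'
#' @param train an `aiwrap_dataset`.
#' @param variant `"L"`, `"LLr"` or `"LR"`.
#' @param interactions logical; expand two-way interaction products in the
#'   embedded stage (`FALSE` for marginal-model runs).
#' @param ga a [ga_config()] for the wrapper search.
#' @param cv a [cv_config()] shared by all real fits.
#' @param ppm a [ppm_config()].
#' @param B bootstrap count for the performance filter.
#' @param seed master seed.
#' @return list of class `aiwrap_result`: `variant`, `q_wrap`, `q_embed`,
#'   `q_final`, `model` (final `aiwrap_model`), `embedded_model`, `wrapper`
#'   (the `aiwrap_wrap`), `fit_counts` (initial / wrapper real-fit counts),
#'   and `seeds` (the derived stage seeds).
#' @export
run_aiwrap <- function(train, variant = c("L", "LLr", "LR"),
                       interactions = TRUE, ga = ga_config(),
                       cv = cv_config(), ppm = ppm_config(), B = 100,
                       seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(inherits(train, "aiwrap_dataset"), ncol(train$X) >= 2,
            nrow(train$X) >= 10)
  seeds <- derive_seeds(seed, 6)
  # one fold assignment shared by every fit in the run, so subset
  # performances are compared on identical splits
  if (is.null(cv$fold_seed)) cv$fold_seed <- seeds[6]
  p <- ncol(train$X)

  # stage 1: initial D_perf and surrogate
  k <- ppm$k_multiplier * p
  set.seed(seeds[1])
  subsets <- sample_random_subsets(p, k, size_law = ppm$size_law)
  dperf <- build_performance_dataset(train, subsets, cv)
  surrogate <- train_ppm(dperf, ppm, seed = seeds[2])

  # stage 2: surrogate-assisted coarse search
  wrap <- ga_wrapper_search(train, dperf, surrogate, ga = ga, cv = cv,
                            ppm_cfg = ppm, seed = seeds[3])

  finish_pipeline(train, wrap, variant, interactions, cv, B,
                  seeds, fit_initial = k)
}

#' Run the Standard Wrapper baseline pipeline
#'
#' The same GA search with a real fit for every candidate (no surrogate, no
#' initial subset sample), followed by the same embedded LASSO stage; no
#' performance filter.
#'
#' @inheritParams run_aiwrap
#' @return an `aiwrap_result` with `variant = "StW"`.
#' @export
run_stw <- function(train, interactions = TRUE, ga = ga_config(),
                    cv = cv_config(), seed = 1L) {
  stopifnot(inherits(train, "aiwrap_dataset"), ncol(train$X) >= 2)
  seeds <- derive_seeds(seed, 6)
  if (is.null(cv$fold_seed)) cv$fold_seed <- seeds[6]
  wrap <- stw_search(train, ga = ga, cv = cv, seed = seeds[3])
  out <- finish_pipeline(train, wrap, "L", interactions, cv, B = 0,
                         seeds, fit_initial = 0L)
  out$variant <- "StW"
  out
}

finish_pipeline <- function(train, wrap, variant, interactions, cv, B,
                            seeds, fit_initial) {
  # stage 3: embedded selection on the expanded q_wrap
  design <- expand_with_interactions(train, wrap$features, interactions)
  emb <- embedded_select(design, train$y, cv)
  q_embed <- emb$q_embed
  if (length(q_embed) == 0) {
    warning("falling back to q_wrap: embedded stage selected nothing")
    q_final_fallback <- wrap$features
  } else {
    q_final_fallback <- NULL
  }

  q_final <- q_embed
  final_model <- emb$model
  filter <- NULL

  # stage 4: performance-based filter (LLr / LR only)
  if (variant %in% c("LLr", "LR") && length(q_embed) >= 2) {
    Xq <- design$x[, q_embed, drop = FALSE]
    imp <- loo_importance(Xq, train$y, B = B, cv = cv, seed = seeds[4])
    thr <- threshold_search(imp, Xq, train$y,
                            technique = if (variant == "LLr") "ols" else "ridge",
                            seed = seeds[5])
    q_final <- thr$q_best
    if (length(q_final) == 0) {
      warning("falling back to q_embed: performance filter kept nothing")
      q_final <- q_embed
    }
    fv <- if (variant == "LLr" && length(q_final) < nrow(train$X)) "LLr" else "LR"
    final_model <- fit_final_model(design$x, train$y, q_final, fv, cv)
    filter <- list(importance = imp, threshold = thr)
  } else if (variant %in% c("LLr", "LR") && length(q_embed) == 1) {
    q_final <- q_embed
    final_model <- fit_final_model(design$x, train$y, q_final,
                                   if (variant == "LLr") "LLr" else "LR", cv)
  }

  structure(list(
    variant = paste0("AIWrap-", variant),
    q_wrap = wrap$features,
    q_embed = q_embed,
    q_final = if (length(q_final)) q_final else q_final_fallback %||% character(0),
    model = final_model,
    embedded_model = emb$model,
    design = design,
    wrapper = wrap,
    filter = filter,
    fit_counts = list(initial = fit_initial, wrapper = wrap$n_fits),
    seeds = seeds), class = "aiwrap_result")
}

#' @export
print.aiwrap_result <- function(x, ...) {
  cat(sprintf("<aiwrap_result %s> |q_wrap|=%d -> |q_embed|=%d -> |q_final|=%d\n",
              x$variant, length(x$q_wrap), length(x$q_embed), length(x$q_final)))
  cat(sprintf("  real fits: %d initial + %d wrapper\n",
              x$fit_counts$initial, x$fit_counts$wrapper))
  invisible(x)
}

#' Predict from a pipeline result
#'
#' Builds the interaction columns the final model needs from the raw feature
#' columns of `newdata`, then predicts with the variant's final model.
#'
#' @param object an `aiwrap_result`.
#' @param newdata matrix/data frame with the original feature columns, or an
#'   `aiwrap_dataset`.
#' @param model which stage's model to use: the variant's `"final"` model or
#'   the `"embedded"` AIWrap-L model.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.aiwrap_result <- function(object, newdata, model = c("final", "embedded"), ...) {
  model <- match.arg(model)
  m <- if (model == "final") object$model else object$embedded_model
  X <- if (inherits(newdata, "aiwrap_dataset")) newdata$X else as.matrix(newdata)
  feats <- names(m$coefficients)
  inter <- grep(":", feats, value = TRUE)
  if (length(inter)) {
    extra <- sapply(strsplit(inter, ":", fixed = TRUE),
                    function(pq) X[, pq[1]] * X[, pq[2]])
    extra <- matrix(extra, nrow = nrow(X), dimnames = list(NULL, inter))
    X <- cbind(X, extra)
  }
  predict(m, X)
}
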