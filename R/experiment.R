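# Evaluation harness: selection F1 against the scenario's target set, test
# RMSE, feature-count summaries, selection-frequency AUC, and replicated
# trials pooled as mean / range / 95% CI.

#' F1 score of a selected feature set against the targets
#'
#' Precision is computed over the selected labels, recall over the targets;
#' interaction labels (`"xi:xj"`) count as features like any other.
#'
#' @param selected character vector of selected labels.
#' @param targets character vector of target labels, or the `targets` list
#'   from [simulate_dataset()].
#' @return F1 in `[0, 1]` (0 when the intersection or the selection is
#'   empty).
#' @export
f1_selection <- function(selected, targets) {
  if (is.list(targets)) targets <- target_labels(targets)
  stopifnot(length(targets) >= 1)
  selected <- unique(selected)
  tp <- length(intersect(selected, targets))
  precision <- if (length(selected) == 0) 0 else tp / length(selected)
  recall <- tp / length(targets)
  if (precision + recall == 0) return(0)
  2 * precision * recall / (precision + recall)
}

#' ROC AUC of selection frequency as a target classifier
#'
#' Uses the rank (Mann-Whitney) formulation with mid-rank tie credit:
#' the probability that a randomly chosen target feature has a higher
#' selection frequency than a randomly chosen noise feature, counting ties
#' as 1/2.
#'
#' @param frequencies named numeric vector: selection count per feature
#'   label across trials (features never selected must appear with 0).
#' @param targets character vector of target labels (or the `targets` list).
#' @return AUC in `[0, 1]`; 0.5 when all frequencies are equal.
#' @export
selection_auc <- function(frequencies, targets) {
  if (is.list(targets)) targets <- target_labels(targets)
  labels <- names(frequencies) %in% targets
  n_pos <- sum(labels)
  n_neg <- sum(!labels)
  stopifnot(n_pos >= 1, n_neg >= 1)
  r <- rank(frequencies)
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

run_method <- function(method, sim, interactions, ga, cv, ppm, B, seed) {
  X <- sim$train$X
  y <- sim$train$y
  switch(method,
    "aiwrap-l" = run_aiwrap(sim$train, "L", interactions, ga, cv, ppm, B, seed),
    "aiwrap-llr" = run_aiwrap(sim$train, "LLr", interactions, ga, cv, ppm, B, seed),
    "aiwrap-lr" = run_aiwrap(sim$train, "LR", interactions, ga, cv, ppm, B, seed),
    "stw" = run_stw(sim$train, interactions, ga, cv, seed),
    "lasso" = {
      # standalone baseline: CV LASSO on the full (optionally fully expanded)
      # design
      design <- expand_with_interactions(sim$train, colnames(X), interactions)
      withr::with_seed(seed, {
        m <- fit_model(design$x, y, "lasso", cv)
      })
      sel <- selected_features(m)
      structure(list(variant = "LASSO", q_wrap = colnames(X), q_embed = sel,
                     q_final = sel, model = m, embedded_model = m,
                     design = design,
                     fit_counts = list(initial = 0L, wrapper = 1L)),
                class = "aiwrap_result")
    },
    stop("unknown method: ", method))
}

#' Replicated simulation experiment
#'
#' For each trial: a fresh train/test draw under the scenario (trial seeds
#' derived from the master seed), each method run on the training data only,
#' and evaluation on the shared test set. Emits both the embedded-stage F1
#' (algorithm comparison before any final filter) and the final-selection
#' F1, test RMSE of the variant's final model, and selected-feature counts;
#' pooled as mean with range (counts) and mean with 95% normal CI (RMSE),
#' plus per-feature selection frequencies and their target-classification
#' AUC.
#'
#' @param scenario an `aiwrap_scenario`.
#' @param methods character vector among `"aiwrap-l"`, `"aiwrap-llr"`,
#'   `"aiwrap-lr"`, `"stw"`, `"lasso"`.
#' @param n_trials number of replicated trials.
#' @param seed master seed.
#' @param ga,cv,ppm,B stage configurations (see [run_aiwrap()]).
#' @return list of class `aiwrap_report`: `trials` (one row per method x
#'   trial), `summary` (pooled per method), `frequencies` (per-method named
#'   selection counts over the final sets), `auc` (per method), `targets`.
#' @export
replicate_experiment <- function(scenario, methods = "aiwrap-l", n_trials = 10,
                                 seed = 1L, ga = ga_config(), cv = cv_config(),
                                 ppm = ppm_config(), B = 100) {
  stopifnot(n_trials >= 1)
  trial_seeds <- derive_seeds(seed, 2 * n_trials)
  interactions <- length(scenario$beta_interaction) > 0
  rows <- list()
  freq <- list()
  targets <- NULL
  for (t in seq_len(n_trials)) {
    scn <- scenario
    scn$seed <- trial_seeds[t]
    sim <- simulate_dataset(scn)
    targets <- sim$targets
    all_labels <- c(colnames(sim$train$X),
                    if (interactions) all_pair_labels(ncol(sim$train$X)))
    for (method in methods) {
      res <- tryCatch(
        run_method(method, sim, interactions, ga, cv, ppm, B,
                   seed = trial_seeds[n_trials + t]),
        error = function(e) {
          warning(sprintf("trial %d method %s failed: %s", t, method,
                          conditionMessage(e)))
          NULL
        })
      if (is.null(res)) next
      yhat <- predict(res, sim$test, model = "final")
      yhat_emb <- predict(res, sim$test, model = "embedded")
      rows[[length(rows) + 1]] <- data.frame(
        method = method, trial = t,
        f1_embedded = f1_selection(res$q_embed, targets),
        f1_final = f1_selection(res$q_final, targets),
        rmse_test = rmse(sim$test$y, yhat),
        rmse_test_embedded = rmse(sim$test$y, yhat_emb),
        n_selected = length(res$q_final),
        n_marginal = sum(!grepl(":", res$q_final)),
        n_interaction = sum(grepl(":", res$q_final)),
        n_fits = res$fit_counts$initial + res$fit_counts$wrapper)
      f <- freq[[method]] %||% stats::setNames(rep(0L, length(all_labels)), all_labels)
      hits <- intersect(res$q_final, names(f))
      f[hits] <- f[hits] + 1L
      freq[[method]] <- f
    }
  }
  trials <- do.call(rbind, rows)
  summary <- do.call(rbind, lapply(split(trials, trials$method), function(d) {
    se <- stats::sd(d$rmse_test) / sqrt(nrow(d))
    data.frame(method = d$method[1], n_trials = nrow(d),
               f1_embedded_mean = mean(d$f1_embedded),
               f1_final_mean = mean(d$f1_final),
               rmse_mean = mean(d$rmse_test),
               rmse_ci_lo = mean(d$rmse_test) - 1.96 * se,
               rmse_ci_hi = mean(d$rmse_test) + 1.96 * se,
               n_selected_mean = mean(d$n_selected),
               n_selected_min = min(d$n_selected),
               n_selected_max = max(d$n_selected),
               n_fits_mean = mean(d$n_fits))
  }))
  rownames(summary) <- NULL
  auc <- vapply(freq, function(f) selection_auc(f, targets), numeric(1))
  structure(list(scenario = scenario$name, trials = trials, summary = summary,
                 frequencies = freq, auc = auc, targets = targets),
            class = "aiwrap_report")
}

all_pair_labels <- function(p) {
  if (p < 2) return(character(0))
  pairs <- utils::combn(p, 2)
  paste0("x", pairs[1, ], ":x", pairs[2, ])
}

#' @export
print.aiwrap_report <- function(x, ...) {
  cat(sprintf("<aiwrap_report %s> %d trials\n", x$scenario,
              max(x$trials$trial)))
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
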