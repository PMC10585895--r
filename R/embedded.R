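# Embedded stage: the coarse feature set is expanded with all two-way
# interaction products and refined by a cross-validated LASSO; its nonzero
# support is q_embed and the fitted model is the AIWrap-L predictor.

#' Expand a feature set with two-way interaction products
#'
#' Builds the augmented design: the base columns of `features` (in original
#' column order) plus one product column `xi:xj` for every unordered pair
#' `i < j` within the set, computed from the raw (unstandardized) columns.
#' With `m` base features the catalog has `m (m - 1) / 2` interaction
#' columns.
#'
#' @param train an `aiwrap_dataset` (or any object with an `X` matrix).
#' @param features character vector of base feature labels.
#' @param interactions logical; `FALSE` returns the base design only
#'   (marginal-model mode).
#' @return list of class `aiwrap_design`: `x` (combined matrix),
#'   `base_features`, `interaction_features`.
#' @export
expand_with_interactions <- function(train, features, interactions = TRUE) {
  stopifnot(length(features) >= 1, all(features %in% colnames(train$X)))
  # canonical order: original column order, lower index first in each pair
  features <- colnames(train$X)[sort(match(features, colnames(train$X)))]
  base <- train$X[, features, drop = FALSE]
  inter_labels <- character(0)
  inter <- NULL
  m <- length(features)
  if (interactions && m >= 2) {
    pairs <- utils::combn(m, 2)
    inter <- matrix(0, nrow = nrow(base), ncol = ncol(pairs))
    inter_labels <- character(ncol(pairs))
    for (k in seq_len(ncol(pairs))) {
      i <- pairs[1, k]; j <- pairs[2, k]
      inter[, k] <- base[, i] * base[, j]
      inter_labels[k] <- paste0(features[i], ":", features[j])
    }
    colnames(inter) <- inter_labels
  }
  x <- if (is.null(inter)) base else cbind(base, inter)
  structure(list(x = x, base_features = features,
                 interaction_features = inter_labels),
            class = "aiwrap_design")
}

#' Embedded LASSO selection over an augmented design
#'
#' Fits a 10-fold cross-validated LASSO on the augmented design; the labels
#' with nonzero coefficients (|beta| > 1e-8) form `q_embed`, and the fitted
#' model is retained as the AIWrap-L predictive model.
#'
#' @param design an `aiwrap_design` from [expand_with_interactions()].
#' @param y outcome vector.
#' @param cv a [cv_config()].
#' @return list of class `aiwrap_embedded`: `q_embed` (selected labels) and
#'   `model` (the `aiwrap_model`).
#' @export
embedded_select <- function(design, y, cv = cv_config()) {
  stopifnot(inherits(design, "aiwrap_design"), ncol(design$x) >= 1)
  model <- fit_model(design$x, y, "lasso", cv)
  q_embed <- selected_features(model)
  if (length(q_embed) == 0) {
    warning("embedded LASSO selected no features; model is intercept-only")
  }
  structure(list(q_embed = q_embed, model = model), class = "aiwrap_embedded")
}
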