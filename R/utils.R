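#' @keywords internal
"_PACKAGE"

# package-level state: audit counter for real base-model fits
the <- new.env(parent = emptyenv())
the$fit_count <- 0L

#' Audit counter for real model fits
#'
#' Every call to [fit_model()] increments a package-level counter. The counter
#' makes the surrogate's model-fit economy auditable: wrap any pipeline call
#' between [reset_fit_count()] and [fit_count()] to count how many real
#' (non-surrogate) model fits it performed.
#'
#' @return `fit_count()` returns the current count (integer);
#'   `reset_fit_count()` resets it to zero and returns the previous value
#'   invisibly.
#' @export
fit_count <- function() the$fit_count

#' @rdname fit_count
#' @export
reset_fit_count <- function() {
  old <- the$fit_count
  the$fit_count <- 0L
  invisible(old)
}

bump_fit_count <- function() {
  the$fit_count <- the$fit_count + 1L
  invisible(NULL)
}

#' Derive stage seeds from a master seed
#'
#' Deterministically expands one master seed into `n` independent stage seeds
#' (all below `.Machine$integer.max`) without disturbing the caller's RNG
#' state. Used by the pipeline so that every stage logs a reproducible seed.
#'
#' @param master integer master seed.
#' @param n number of seeds to derive.
#' @return integer vector of length `n`.
#' @export
derive_seeds <- function(master, n) {
  withr::with_seed(as.integer(master), sample.int(.Machine$integer.max, n))
}

# Fold assignment for cross-validation; seeded (without touching the global
# stream) when fold_seed is given, otherwise drawn from the current stream.
make_folds <- function(n, n_folds, fold_seed = NULL) {
  stopifnot(n_folds >= 2, n_folds <= n)
  draw <- function() sample(rep_len(seq_len(n_folds), n))
  if (is.null(fold_seed)) draw() else withr::with_seed(as.integer(fold_seed), draw())
}

`%||%` <- function(a, b) if (is.null(a)) b else a

mask_key <- function(mask) paste(as.integer(mask), collapse = "")
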