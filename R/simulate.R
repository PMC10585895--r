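# Simulation-study data generator: correlated multivariate-normal features
# with marginal or pairwise-interaction linear outcome models.

#' Define a simulation scenario
#'
#' A scenario fixes the data-generating process for one simulated study
#' condition: `p` standard-normal features with a compound-symmetry
#' correlation `rho_block` among the first `min(15, p)` features, and a
#' continuous outcome
#' \deqn{y = \beta_0 + \sum_i \beta_i x_i + \sum_{i<j} \beta_{ij} x_i x_j + \epsilon,
#'   \quad \epsilon \sim N(0, \sigma^2).}
#' Marginal scenarios have an empty interaction coefficient set.
#'
#' @param name scenario label, e.g. `"1_M"`.
#' @param p number of candidate features.
#' @param n_train,n_test training and test sample sizes.
#' @param sigma noise standard deviation (>= 0).
#' @param beta_marginal numeric vector of length `p` of marginal coefficients.
#' @param beta_interaction named numeric vector of interaction coefficients;
#'   names are `"xi:xj"` with `i < j` (empty for marginal scenarios).
#' @param beta0 intercept (defaults to 0).
#' @param rho_block within-block correlation, `0 <= rho_block < 1`.
#' @param seed RNG seed used by [simulate_dataset()].
#' @return an object of class `aiwrap_scenario`.
#' @seealso [standard_scenarios()], [simulate_dataset()]
#' @export
simulation_scenario <- function(name, p, n_train, n_test = 500, sigma = 0.25,
                                beta_marginal = numeric(p),
                                beta_interaction = numeric(0),
                                beta0 = 0, rho_block = 0.5, seed = 1L) {
  stopifnot(p >= 1, n_train >= 1, n_test >= 1, sigma >= 0)
  if (rho_block < 0 || rho_block >= 1) {
    stop("rho_block must lie in [0, 1) to define a valid correlation block")
  }
  stopifnot(length(beta_marginal) == p)
  if (length(beta_interaction)) {
    stopifnot(!is.null(names(beta_interaction)))
    idx <- interaction_indices(names(beta_interaction))
    if (any(idx[, 1] >= idx[, 2]) || any(idx > p) || any(idx < 1)) {
      stop("interaction names must be 'xi:xj' with 1 <= i < j <= p")
    }
  }
  structure(
    list(name = name, p = as.integer(p), n_train = as.integer(n_train),
         n_test = as.integer(n_test), sigma = sigma, beta0 = beta0,
         beta_marginal = beta_marginal, beta_interaction = beta_interaction,
         rho_block = rho_block, seed = as.integer(seed)),
    class = "aiwrap_scenario")
}

#' @export
print.aiwrap_scenario <- function(x, ...) {
  cat(sprintf("<aiwrap_scenario %s> p=%d, n_train=%d, n_test=%d, sigma=%g, rho_block=%g\n",
              x$name, x$p, x$n_train, x$n_test, x$sigma, x$rho_block))
  cat(sprintf("  %d marginal targets, %d interaction targets, seed=%d\n",
              sum(abs(x$beta_marginal) > 0), length(x$beta_interaction), x$seed))
  invisible(x)
}

# "x2:x7" -> rbind(c(2, 7), ...)
interaction_indices <- function(labels) {
  parts <- strsplit(labels, ":", fixed = TRUE)
  t(vapply(parts, function(s) as.integer(sub("^x", "", s)), integer(2)))
}

#' Block compound-symmetry covariance matrix
#'
#' Unit-variance covariance with constant correlation `rho_block` among the
#' first `min(15, p)` features and independence elsewhere.
#'
#' @param p matrix dimension.
#' @param rho_block within-block correlation, `0 <= rho_block < 1`.
#' @return a `p x p` symmetric positive-definite matrix.
#' @export
build_covariance <- function(p, rho_block = 0.5) {
  stopifnot(p >= 1)
  if (rho_block < 0 || rho_block >= 1) {
    stop("rho_block must lie in [0, 1): the block would not be a correlation matrix")
  }
  sigma <- diag(p)
  b <- min(15L, p)
  sigma[seq_len(b), seq_len(b)] <- rho_block
  diag(sigma) <- 1
  sigma
}

new_dataset <- function(X, y) {
  colnames(X) <- paste0("x", seq_len(ncol(X)))
  structure(list(X = X, y = as.numeric(y), feature_names = colnames(X)),
            class = "aiwrap_dataset")
}

#' Construct a dataset object from a feature matrix and outcome
#'
#' @param X numeric matrix or data frame of features (columns renamed
#'   `x1..xp`).
#' @param y numeric outcome vector, `length(y) == nrow(X)`.
#' @return an object of class `aiwrap_dataset` with elements `X`, `y`,
#'   `feature_names`.
#' @export
as_dataset <- function(X, y) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  stopifnot(nrow(X) == length(y), !anyNA(X), !anyNA(y))
  new_dataset(X, as.numeric(y))
}

#' @export
print.aiwrap_dataset <- function(x, ...) {
  cat(sprintf("<aiwrap_dataset> n=%d, p=%d\n", nrow(x$X), ncol(x$X)))
  invisible(x)
}

scenario_outcome <- function(scn, X) {
  y <- scn$beta0 + drop(X %*% scn$beta_marginal)
  if (length(scn$beta_interaction)) {
    idx <- interaction_indices(names(scn$beta_interaction))
    for (r in seq_len(nrow(idx))) {
      y <- y + scn$beta_interaction[r] * X[, idx[r, 1]] * X[, idx[r, 2]]
    }
  }
  y
}

#' Simulate train/test datasets under a scenario
#'
#' Draws independent train and test samples with rows
#' \eqn{x \sim N(0, \Sigma)}, \eqn{\Sigma} from [build_covariance()], and the
#' scenario's linear (+ pairwise interaction) outcome with Gaussian noise.
#' Fully reproducible from `scenario$seed`.
#'
#' @param scenario an `aiwrap_scenario`.
#' @return a list with elements `train`, `test` (both `aiwrap_dataset`) and
#'   `targets` (list of `marginal` and `interaction` target labels).
#' @export
simulate_dataset <- function(scenario) {
  stopifnot(inherits(scenario, "aiwrap_scenario"))
  sigma_mat <- build_covariance(scenario$p, scenario$rho_block)
  withr::with_seed(scenario$seed, {
    draw <- function(n) {
      X <- MASS::mvrnorm(n, mu = rep(0, scenario$p), Sigma = sigma_mat)
      y <- scenario_outcome(scenario, X) + stats::rnorm(n, sd = scenario$sigma)
      new_dataset(X, y)
    }
    train <- draw(scenario$n_train)
    test <- draw(scenario$n_test)
  })
  targets <- list(
    marginal = paste0("x", which(abs(scenario$beta_marginal) > 0)),
    interaction = names(scenario$beta_interaction) %||% character(0))
  list(train = train, test = test, targets = targets)
}

#' All target labels of a scenario's target set
#'
#' @param targets the `targets` element returned by [simulate_dataset()].
#' @return character vector of marginal plus interaction labels.
#' @export
target_labels <- function(targets) {
  c(targets$marginal, targets$interaction)
}

# alternating +/-0.5 over the first 10 features, starting positive
alternating_beta <- function(p, n_nonzero = 10) {
  beta <- numeric(p)
  beta[seq_len(n_nonzero)] <- 0.5 * (-1)^(seq_len(n_nonzero) - 1)
  beta
}

#' The seven standard simulation scenarios
#'
#' Four marginal scenarios (`1_M`-`4_M`) and three pairwise-interaction
#' scenarios (`1_I`-`3_I`). All use sigma = 0.25, a 500-sample test set,
#' correlation 0.5 among the first `min(15, p)` features, and alternating
#' coefficients +/-0.5 on the first ten features (and, for interaction
#' scenarios, on the nine adjacent pairs `x1:x2 ... x9:x10`).
#'
#' @param seed base seed stored in each scenario (replications typically
#'   override it per trial).
#' @return named list of `aiwrap_scenario` objects.
#' @export
standard_scenarios <- function(seed = 1L) {
  marg <- list(`1_M` = c(50, 50), `2_M` = c(50, 100),
               `3_M` = c(100, 75), `4_M` = c(100, 100))
  inter <- list(`1_I` = 15, `2_I` = 25, `3_I` = 50)
  out <- list()
  for (nm in names(marg)) {
    p <- marg[[nm]][1]
    out[[nm]] <- simulation_scenario(nm, p = p, n_train = marg[[nm]][2],
                                     beta_marginal = alternating_beta(p),
                                     seed = seed)
  }
  pair_labels <- paste0("x", 1:9, ":x", 2:10)
  beta_ij <- stats::setNames(0.5 * (-1)^(0:8), pair_labels)
  for (nm in names(inter)) {
    p <- inter[[nm]]
    out[[nm]] <- simulation_scenario(nm, p = p, n_train = 100,
                                     beta_marginal = alternating_beta(p),
                                     beta_interaction = beta_ij,
                                     seed = seed)
  }
  out
}
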