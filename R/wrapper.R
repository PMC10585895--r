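# Coarse wrapper stage: a binary-mask genetic algorithm searches the subset
# space. AIWrap scores candidates through the PPM surrogate and spends real
# model fits only on candidates whose predicted performance reaches the best
# quartile of known true performances; the Standard Wrapper (StW) fits every
# candidate for real.

#' Genetic-algorithm configuration
#'
#' Defaults follow standard practice for feature-mask GAs: tournament
#' selection (size 3), uniform crossover with probability 0.8, per-bit
#' mutation rate `1/p`, single-individual elitism.
#'
#' @param pop population size (>= 2).
#' @param generations maximum number of generations (default 100).
#' @param p_crossover crossover probability.
#' @param mutation_rate per-bit mutation probability (default `1/p`).
#' @param tournament tournament size.
#' @param elitism number of best individuals copied unchanged.
#' @param val_quantile quantile of known true performances used as the
#'   validation gate (default 0.25: the best quarter, since lower RMSE is
#'   better).
#' @return list of class `aiwrap_ga`.
#' @export
ga_config <- function(pop = 50, generations = 100, p_crossover = 0.8,
                      mutation_rate = NULL, tournament = 3, elitism = 1,
                      val_quantile = 0.25) {
  stopifnot(pop >= 2, generations >= 1,
            p_crossover >= 0, p_crossover <= 1,
            val_quantile > 0, val_quantile < 1, elitism >= 0)
  structure(list(pop = as.integer(pop), generations = as.integer(generations),
                 p_crossover = p_crossover, mutation_rate = mutation_rate,
                 tournament = as.integer(tournament),
                 elitism = as.integer(elitism), val_quantile = val_quantile),
            class = "aiwrap_ga")
}

#' Validation gate threshold over known performances
#'
#' The gate is the 25th percentile (linear interpolation) of all known true
#' performances: candidates whose predicted RMSE is at or below it are in the
#' best quarter and earn a real model fit.
#'
#' @param performances numeric vector of known true performances (RMSE
#'   scale).
#' @param q gate quantile (default 0.25).
#' @return the threshold value.
#' @export
validation_threshold <- function(performances, q = 0.25) {
  if (length(performances) == 0) stop("no known performances")
  unname(stats::quantile(performances, probs = q, type = 7))
}

repair_mask <- function(mask) {
  if (sum(mask) == 0) mask[sample.int(length(mask), 1)] <- 1L
  mask
}

tournament_pick <- function(fitness, size) {
  contenders <- sample.int(length(fitness), size, replace = TRUE)
  contenders[which.min(fitness[contenders])]
}

evolve_population <- function(masks, fitness, ga, mutation_rate) {
  pop <- nrow(masks)
  p <- ncol(masks)
  nxt <- matrix(0L, nrow = pop, ncol = p)
  n_elite <- min(ga$elitism, pop)
  if (n_elite > 0) {
    nxt[seq_len(n_elite), ] <- masks[order(fitness)[seq_len(n_elite)], , drop = FALSE]
  }
  i <- n_elite
  while (i < pop) {
    pa <- masks[tournament_pick(fitness, ga$tournament), ]
    pb <- masks[tournament_pick(fitness, ga$tournament), ]
    if (stats::runif(1) < ga$p_crossover) {
      swap <- stats::runif(p) < 0.5
      child1 <- ifelse(swap, pb, pa)
      child2 <- ifelse(swap, pa, pb)
    } else {
      child1 <- pa
      child2 <- pb
    }
    for (child in list(child1, child2)) {
      if (i >= pop) break
      flip <- stats::runif(p) < mutation_rate
      child <- ifelse(flip, 1L - child, child)
      i <- i + 1
      nxt[i, ] <- repair_mask(as.integer(child))
    }
  }
  nxt
}

#' Surrogate-assisted GA wrapper search
#'
#' Runs the coarse wrapper stage. Each generation: (1) the population is
#' scored by [predict_performance()]; (2) candidates whose predicted
#' performance reaches [validation_threshold()] of all known true
#' performances are validated with a real fit (previously validated masks
#' keep their first recorded performance and cost no new fit), and `D_perf`
#' gains the new rows; (3) the PPM is retrained on the extended `D_perf`;
#' (4) selection/crossover/mutation produce the next population, using the
#' true performance as fitness where known and the prediction otherwise. If
#' no candidate passes the gate, the generation's best-predicted candidate is
#' force-validated so a validated optimum always exists. The search stops
#' after `ga$generations` generations and returns the best validated subset
#' ever seen.
#'
#' With `use_ppm = FALSE` the engine degenerates to the Standard Wrapper:
#' every candidate is fitted for real and the surrogate is never consulted
#' (see [stw_search()]).
#'
#' @param train an `aiwrap_dataset`.
#' @param dperf an `aiwrap_dperf` of already-validated subsets (required when
#'   `use_ppm = TRUE`; optional otherwise).
#' @param ppm a trained [train_ppm()] surrogate (required when
#'   `use_ppm = TRUE`).
#' @param ga a [ga_config()].
#' @param cv a [cv_config()] for the real validation fits.
#' @param ppm_cfg a [ppm_config()] used for retraining.
#' @param use_ppm logical; `FALSE` bypasses the surrogate entirely.
#' @param seed optional seed for the whole search.
#' @return list of class `aiwrap_wrap`: `q_wrap` (best validated mask),
#'   `features` (its labels), `c_true` (its performance), `dperf` (updated),
#'   `ppm` (last retrain), `trace` (per-generation data frame with columns
#'   `generation`, `best_pred`, `best_true`, `n_validated`, `n_fits`,
#'   `forced`), and `n_fits` (total real fits spent by the search).
#' @export
ga_wrapper_search <- function(train, dperf = NULL, ppm = NULL,
                              ga = ga_config(), cv = cv_config(),
                              ppm_cfg = ppm_config(), use_ppm = TRUE,
                              seed = NULL) {
  stopifnot(inherits(train, "aiwrap_dataset"))
  if (use_ppm && (is.null(dperf) || is.null(ppm))) {
    stop("surrogate mode needs a performance dataset and a trained PPM")
  }
  if (!is.null(seed)) set.seed(as.integer(seed))
  p <- ncol(train$X)
  mutation_rate <- ga$mutation_rate %||% (1 / p)
  if (is.null(dperf)) {
    dperf <- new_dperf(matrix(0L, 0, p), numeric(0), character(0))
  }

  cache <- new.env(hash = TRUE, parent = emptyenv())
  for (j in seq_along(dperf$c)) {
    key <- mask_key(dperf$masks[j, ])
    if (is.null(cache[[key]])) cache[[key]] <- dperf$c[j]
  }
  best_c <- Inf
  best_mask <- NULL
  if (length(dperf$c)) {
    j0 <- which.min(dperf$c)
    best_c <- dperf$c[j0]
    best_mask <- as.integer(dperf$masks[j0, ])
  }

  masks <- sample_random_subsets(p, ga$pop)
  trace <- vector("list", ga$generations)
  total_fits <- 0L

  for (gen in seq_len(ga$generations)) {
    keys <- apply(masks, 1, mask_key)
    cpred <- if (use_ppm) predict_performance(ppm, masks) else rep(NA_real_, ga$pop)
    forced <- FALSE
    if (use_ppm) {
      thr <- validation_threshold(dperf$c, ga$val_quantile)
      to_validate <- which(cpred <= thr)
      if (length(to_validate) == 0) {
        to_validate <- which.min(cpred)
        forced <- TRUE
      }
    } else {
      to_validate <- seq_len(ga$pop)
    }

    n_new <- 0L
    for (i in to_validate) {
      ci <- cache[[keys[i]]]
      if (is.null(ci)) {
        ci <- eval_subset(train, masks[i, ], cv)
        n_new <- n_new + 1L
        cache[[keys[i]]] <- ci
        dperf <- dperf_add(dperf, masks[i, ], ci)
      }
      if (ci < best_c) {
        best_c <- ci
        best_mask <- as.integer(masks[i, ])
      }
    }
    total_fits <- total_fits + n_new

    known <- vapply(keys, function(k) cache[[k]] %||% NA_real_, numeric(1))
    fitness <- ifelse(is.na(known), cpred, known)

    if (use_ppm && n_new > 0) {
      ppm <- train_ppm(dperf, ppm_cfg)
    }

    trace[[gen]] <- data.frame(
      generation = gen,
      best_pred = if (use_ppm) min(cpred) else NA_real_,
      best_true = best_c,
      n_validated = length(to_validate),
      n_fits = n_new,
      forced = forced)

    if (gen < ga$generations) {
      masks <- evolve_population(masks, fitness, ga, mutation_rate)
    }
  }

  structure(list(
    q_wrap = best_mask,
    features = colnames(train$X)[best_mask > 0],
    c_true = best_c,
    dperf = dperf,
    ppm = if (use_ppm) ppm else NULL,
    trace = do.call(rbind, trace),
    n_fits = total_fits), class = "aiwrap_wrap")
}

#' Standard Wrapper baseline search
#'
#' The identical genetic algorithm, but every candidate subset is evaluated
#' by a real model fit: no surrogate, no validation gate. Equivalent to
#' [ga_wrapper_search()] with `use_ppm = FALSE` and no initial `D_perf`,
#' which makes the surrogate's fit economy directly measurable against the
#' same search trajectory.
#'
#' @inheritParams ga_wrapper_search
#' @return an `aiwrap_wrap`, as [ga_wrapper_search()].
#' @export
stw_search <- function(train, ga = ga_config(), cv = cv_config(), seed = NULL) {
  ga_wrapper_search(train, dperf = NULL, ppm = NULL, ga = ga, cv = cv,
                    use_ppm = FALSE, seed = seed)
}

#' @export
print.aiwrap_wrap <- function(x, ...) {
  cat(sprintf("<aiwrap_wrap> |q_wrap|=%d, c_true=%.4g, %d real fits over %d generations\n",
              sum(x$q_wrap), x$c_true, x$n_fits, nrow(x$trace)))
  invisible(x)
}
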