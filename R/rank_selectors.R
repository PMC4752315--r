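# Ranking-based and population-based selectors compared against SFS:
# Gaussian-kernel SVM-RFE with class-imbalance weights, ReliefF feature
# weighting, and a GA-KNN subset search. RFE and ReliefF produce a full
# ranking from which the top k probes are taken (k matched per gene to the
# SFS selection size); the GA returns a subset directly.

#' Class-imbalance weights for the SVM penalty
#'
#' Solves `n0 * w0 = n1 * w1` with `w1 = 1`, where `n0`/`n1` are the down
#' and up sample counts, so misclassifying the minority class costs more.
#'
#' @param labels A [label_vector()] with both classes present.
#' @return A `class_weights` list with `n0`, `n1`, `w0`, `w1`.
#' @export
balance_weights <- function(labels) {
  counts <- table(labels$labels)
  n0 <- counts[["down"]]
  n1 <- counts[["up"]]
  if (n0 == 0 || n1 == 0) {
    abort("balance_weights needs both classes present")
  }
  structure(list(n0 = n0, n1 = n1, w0 = n1 / n0, w1 = 1),
            class = "class_weights")
}

#' Rank probes by Gaussian-kernel SVM recursive feature elimination
#'
#' Repeatedly fits a class-weighted Gaussian-kernel SVM on the surviving
#' features and eliminates the feature whose removal from the kernel
#' changes the dual objective the least (alphas held fixed) — a constant
#' feature leaves the kernel unchanged and scores exactly 0. Ties are
#' broken by eliminating the higher candidate index first, so duplicated
#' columns end up on adjacent ranks with the lower index ranked better.
#'
#' @param candidates Ordered character vector of probe ids.
#' @param M A [methyl_matrix()].
#' @param labels A [label_vector()] with both classes present.
#' @param weights Optional [balance_weights()] result; computed from
#'   `labels` when NULL.
#' @param cost SVM box constraint.
#' @param seed Unused by the deterministic solver; kept for the selector
#'   contract.
#' @return Character vector: all candidates, best-ranked first.
#' @export
svm_rfe_rank <- function(candidates, M, labels, weights = NULL, cost = 1,
                         seed = NULL) {
  if (length(candidates) < 2) {
    abort("svm_rfe_rank needs at least 2 candidate probes")
  }
  if (is.null(weights)) {
    weights <- balance_weights(labels)
  }
  x <- t(unclass(M)[candidates, labels$sample_ids, drop = FALSE])
  y <- labels$labels
  cw <- c(down = weights$w0, up = weights$w1)
  surviving <- seq_along(candidates)
  eliminated <- integer(0)
  while (length(surviving) > 1) {
    xs <- x[, surviving, drop = FALSE]
    fit <- rfe_svm_fit(xs, y, cw, cost)
    sv <- xs[fit$index, , drop = FALSE]
    a <- as.numeric(fit$coefs) # alpha_i * y_i over support vectors
    gamma <- fit$gamma
    d2 <- sq_dist(sv)
    j_full <- drop(crossprod(a, exp(-gamma * d2) %*% a))
    score <- vapply(seq_along(surviving), function(f) {
      df <- outer(sv[, f], sv[, f], "-")^2
      j_minus <- drop(crossprod(a, exp(-gamma * (d2 - df)) %*% a))
      abs(j_full - j_minus)
    }, numeric(1))
    # min score eliminated; ties -> higher candidate index goes first
    worst <- surviving[score == min(score)]
    drop_idx <- max(worst)
    eliminated <- c(drop_idx, eliminated)
    surviving <- setdiff(surviving, drop_idx)
  }
  candidates[c(surviving, eliminated)]
}

rfe_svm_fit <- function(x, y, class_weights, cost) {
  fit_once <- function(tol) {
    e1071::svm(x = x, y = y, kernel = "radial", cost = cost,
               class.weights = class_weights, scale = FALSE,
               tolerance = tol)
  }
  tryCatch(fit_once(0.001), error = function(e) {
    tryCatch(fit_once(0.01), error = function(e2) {
      abort(paste0("SVM fit failed in RFE even with relaxed tolerance: ",
                   conditionMessage(e2)))
    })
  })
}

sq_dist <- function(x) {
  s <- rowSums(x^2)
  d2 <- outer(s, s, "+") - 2 * tcrossprod(x)
  d2[d2 < 0] <- 0
  d2
}

#' ReliefF feature weights
#'
#' Iterates over instances (by default every sample once, in a seeded
#' shuffle); for each instance the k nearest same-class samples (hits) and
#' k nearest other-class samples (misses) are found by Euclidean distance
#' over all candidate features, and each feature's weight is updated by
#' subtracting its mean squared difference to the hits and adding the mean
#' squared difference to the misses. Updates are divided by the number of
#' iterations; with a single iteration and k = 1 the update is exactly
#' `-(x - h)^2 + (x - m)^2`.
#'
#' @param candidates Ordered character vector of probe ids.
#' @param M A [methyl_matrix()].
#' @param labels A [label_vector()].
#' @param k_neighbors Number of hits/misses averaged (reduced per class
#'   with a warning when a class is too small).
#' @param n_iterations Number of instance updates; default: one pass over
#'   all samples.
#' @param seed Seed for the instance shuffle.
#' @param instances Optional character vector of sample ids to iterate
#'   over, in order (overrides the shuffle; useful for worked examples).
#' @return A `relieff_state`: `weights` (named by probe), `k_neighbors`,
#'   `n_iterations`, `seed`.
#' @export
relieff_weights <- function(candidates, M, labels, k_neighbors = 1,
                            n_iterations = NULL, seed = 450,
                            instances = NULL) {
  x <- t(unclass(M)[candidates, labels$sample_ids, drop = FALSE])
  y <- labels$labels
  n <- nrow(x)
  if (length(unique(y)) < 2) {
    abort("relieff_weights needs both classes present")
  }
  if (is.null(instances)) {
    order_idx <- with_seed(seed, sample(n))
    if (is.null(n_iterations)) {
      n_iterations <- n
    }
    idx <- rep_len(order_idx, n_iterations)
  } else {
    idx <- match(instances, labels$sample_ids)
    if (anyNA(idx)) {
      abort("unknown sample id in `instances`")
    }
    n_iterations <- length(idx)
  }
  d2 <- sq_dist(x)
  w <- numeric(ncol(x))
  warned <- FALSE
  for (i in idx) {
    same <- which(y == y[i] & seq_len(n) != i)
    other <- which(y != y[i])
    k_hit <- min(k_neighbors, length(same))
    k_miss <- min(k_neighbors, length(other))
    if ((k_hit < k_neighbors || k_miss < k_neighbors) && !warned) {
      warn("class too small for k neighbours; k reduced for that class")
      warned <- TRUE
    }
    if (k_hit == 0 || k_miss == 0) {
      next
    }
    hits <- same[order(d2[i, same], labels$sample_ids[same])][seq_len(k_hit)]
    misses <- other[order(d2[i, other],
                          labels$sample_ids[other])][seq_len(k_miss)]
    hit_diff <- colMeans((x[hits, , drop = FALSE] -
                            matrix(x[i, ], k_hit, ncol(x), byrow = TRUE))^2)
    miss_diff <- colMeans((x[misses, , drop = FALSE] -
                             matrix(x[i, ], k_miss, ncol(x),
                                    byrow = TRUE))^2)
    w <- w + (-hit_diff + miss_diff) / n_iterations
  }
  structure(list(weights = setNames(w, candidates),
                 k_neighbors = k_neighbors, n_iterations = n_iterations,
                 seed = seed),
            class = "relieff_state")
}

#' Rank probes by ReliefF weight
#'
#' @param state A `relieff_state` from [relieff_weights()].
#' @return Character vector of probe ids, highest weight first (ties by
#'   candidate order).
#' @export
relieff_rank <- function(state) {
  names(state$weights)[order(-state$weights, seq_along(state$weights))]
}

#' GA-KNN fitness
#'
#' `resub_loss / (n_total - n_selected)`: the resubstitution loss of a KNN
#' classifier on the selected features, divided by the number of
#' *unselected* features, so that the denominator penalizes large subsets.
#' Masks selecting none or all features get `Inf`.
#'
#' @param resub_loss Misclassified fraction on the training data.
#' @param n_total Total number of candidate features N.
#' @param n_selected Number of selected features S.
#' @return Numeric fitness (lower is better).
#' @export
ga_fitness <- function(resub_loss, n_total, n_selected) {
  if (n_selected == 0 || n_selected >= n_total) {
    return(Inf)
  }
  resub_loss / (n_total - n_selected)
}

#' GA search configuration
#'
#' @param population_size,n_generations GA size parameters.
#' @param mutation_rate Per-bit flip probability; default `1/N` set at run
#'   time.
#' @param crossover_rate Probability of uniform crossover per offspring.
#' @param elitism_count Best individuals copied unchanged each generation.
#' @param tournament_size Tournament selection size.
#' @param k_neighbors KNN size for the resubstitution loss.
#' @param seed RNG seed.
#' @return A `ga_config` list.
#' @export
ga_config <- function(population_size = 50, n_generations = 100,
                      mutation_rate = NULL, crossover_rate = 0.8,
                      elitism_count = 2, tournament_size = 3,
                      k_neighbors = 1, seed = 450) {
  stopifnot(population_size >= 2, crossover_rate >= 0, crossover_rate <= 1)
  structure(list(population_size = as.integer(population_size),
                 n_generations = as.integer(n_generations),
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 elitism_count = as.integer(elitism_count),
                 tournament_size = as.integer(tournament_size),
                 k_neighbors = as.integer(k_neighbors),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Select probes with a genetic algorithm over probe subsets
#'
#' Binary-mask GA minimizing [ga_fitness()] with a KNN resubstitution
#' loss. Tournament selection, uniform crossover, per-bit mutation and
#' elitism; fully deterministic given `config$seed`. Note that with
#' `k_neighbors = 1` the resubstitution loss is 0 for any mask without
#' duplicated feature vectors across classes, so fitness then depends on
#' the subset size alone — a degeneracy of the stated objective that is
#' kept as specified.
#'
#' @param candidates Ordered character vector of probe ids.
#' @param M A [methyl_matrix()].
#' @param labels A [label_vector()] with both classes present.
#' @param config A [ga_config()].
#' @return A `probe_selection`; `final_cv_error` holds the best mask's
#'   resubstitution loss and `trace` the best fitness per generation.
#' @export
ga_knn_select <- function(candidates, M, labels, config = ga_config()) {
  x <- t(unclass(M)[candidates, labels$sample_ids, drop = FALSE])
  y <- labels$labels
  n_feat <- length(candidates)
  mu <- config$mutation_rate %||% (1 / n_feat)
  spec <- classifier_spec("knn", k_neighbors = config$k_neighbors)

  resub <- function(mask) {
    model <- fit_classifier(spec, x[, mask, drop = FALSE], y)
    misclassification_count(model, x[, mask, drop = FALSE], y) / length(y)
  }
  fitness <- function(mask) {
    s <- sum(mask)
    if (s == 0 || s >= n_feat) {
      return(Inf)
    }
    ga_fitness(resub(mask), n_feat, s)
  }

  res <- with_seed(config$seed, {
    pop <- lapply(seq_len(config$population_size), function(i) {
      stats::runif(n_feat) < 0.5
    })
    fit <- vapply(pop, fitness, numeric(1))
    best_trace <- numeric(config$n_generations)
    for (gen in seq_len(config$n_generations)) {
      ord <- order(fit)
      elite <- pop[ord[seq_len(min(config$elitism_count, length(pop)))]]
      offspring <- lapply(
        seq_len(config$population_size - length(elite)), function(i) {
          p1 <- pop[[tournament(fit, config$tournament_size)]]
          p2 <- pop[[tournament(fit, config$tournament_size)]]
          child <- if (stats::runif(1) < config$crossover_rate) {
            pick <- stats::runif(n_feat) < 0.5
            ifelse(pick, p1, p2)
          } else {
            p1
          }
          xor(child, stats::runif(n_feat) < mu)
        })
      pop <- c(elite, offspring)
      fit <- vapply(pop, fitness, numeric(1))
      best_trace[gen] <- min(fit)
    }
    best <- pop[[which.min(fit)]]
    list(mask = best, fitness = min(fit), trace = best_trace)
  })

  selected <- candidates[res$mask]
  final_loss <- if (is.finite(res$fitness)) resub(res$mask) else NA_real_
  new_probe_selection(
    gene_id = labels$gene_id,
    method = paste0("ga_knn", config$k_neighbors),
    selected = selected,
    final_cv_error = final_loss,
    trace = tibble(round = seq_along(res$trace), candidate = NA_character_,
                   cce = res$trace, accepted = NA))
}

tournament <- function(fit, size) {
  contenders <- sample(length(fit), min(size, length(fit)))
  contenders[which.min(fit[contenders])]
}
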