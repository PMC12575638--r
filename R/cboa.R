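#' Configuration for chaotic bobcat optimisation (CBOA)
#'
#' Wrapper feature selection by a population metaheuristic: bobcat positions
#' in `[0, 1]^m` are binarized to feature subsets and scored by the
#' cross-validated error of a surrogate classifier plus a small sparsity
#' penalty. The objective is *minimized*: `J = (1 - CV accuracy) +
#' alpha * |subset| / m`, so a lower fitness marks a better bobcat, candidate
#' prey are the strictly fitter individuals, and moves are accepted when the
#' new fitness is `<=` the old.
#'
#' @param n_pop Population size (default 30).
#' @param max_iter Iteration budget (default 100).
#' @param threshold Binarization threshold in (0, 1); feature `d` is selected
#'   when the position coordinate exceeds it.
#' @param alpha Sparsity penalty weight (default 0.05); `alpha = 0` gives
#'   pure-accuracy fitness. The per-feature cost `alpha / m` should exceed
#'   the standard error of the repeated-CV accuracy estimate, otherwise
#'   chance accuracy wiggles, not the penalty, decide between near-tied
#'   subsets.
#' @param folds Stratified cross-validation folds for the surrogate.
#' @param cv_repeats Independent fold repetitions averaged per fitness
#'   evaluation; repeating the cross-validation damps fold noise so the
#'   sparsity penalty, not chance accuracy wiggles, decides between
#'   near-tied subsets.
#' @param lambda Ridge penalty of the surrogate logistic model.
#' @param warmup Chaotic-map warm-up iterations discarded per dimension.
#' @param seed Master seed (chaotic initialization, folds, move randomness).
#' @return A `cboa_config` list.
#' @export
cboa_config <- function(n_pop = 30L, max_iter = 100L, threshold = 0.5,
                        alpha = 0.05, folds = 3L, cv_repeats = 5L,
                        lambda = 2, warmup = 50L, seed = 1L) {
  if (n_pop < 2L) stop("population size must be >= 2", call. = FALSE)
  if (max_iter < 1L) stop("need at least one iteration", call. = FALSE)
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  }
  structure(
    list(n_pop = as.integer(n_pop), max_iter = as.integer(max_iter),
         threshold = threshold, alpha = alpha, folds = as.integer(folds),
         cv_repeats = as.integer(cv_repeats), lambda = lambda,
         warmup = as.integer(warmup), seed = as.integer(seed)),
    class = "cboa_config"
  )
}

#' Chaotic population initialization
#'
#' Positions are `x[i, d] = lb[d] + (ub[d] - lb[d]) * c[i, d]` where the
#' `c` values are iterates of the fully chaotic logistic map
#' `c <- 4 c (1 - c)`, seeded per dimension away from its fixed points and
#' warmed up before use, giving a well-spread deterministic start.
#'
#' @param lower,upper Bound vectors (one entry per dimension).
#' @param config A [cboa_config()].
#' @return Numeric matrix `n_pop x length(lower)` of in-bound positions.
#' @export
chaotic_init_population <- function(lower, upper, config) {
  stopifnot(length(lower) == length(upper), all(upper >= lower))
  m <- length(lower)
  with_local_seed(config$seed, {
    C <- matrix(0, config$n_pop, m)
    for (d in seq_len(m)) {
      c0 <- stats::runif(1L)
      # keep clear of the map's fixed/eventually-fixed points
      while (min(abs(c0 - c(0, 0.25, 0.5, 0.75, 1))) < 1e-3) {
        c0 <- stats::runif(1L)
      }
      for (w in seq_len(config$warmup)) c0 <- 4 * c0 * (1 - c0)
      for (i in seq_len(config$n_pop)) {
        c0 <- 4 * c0 * (1 - c0)
        C[i, d] <- c0
      }
    }
    sweep(sweep(C, 2L, upper - lower, "*"), 2L, lower, "+")
  })
}

#' Binarize a continuous position into a feature subset
#'
#' Feature `d` is selected iff `position[d] > threshold`. If no coordinate
#' exceeds the threshold the subset is repaired to the single largest
#' coordinate, so an evaluated subset is never empty.
#'
#' @param position Numeric vector in `[0, 1]^m`.
#' @param threshold Cut point in (0, 1).
#' @return Logical mask of length `m` with at least one `TRUE`.
#' @export
binarize_position <- function(position, threshold = 0.5) {
  mask <- position > threshold
  if (!any(mask)) mask[which.max(position)] <- TRUE
  mask
}

#' Wrapper fitness of a position
#'
#' `J = (1 - CV accuracy of the surrogate on the binarized subset) +
#' alpha * |subset| / m`; lower is better.
#'
#' @param position Numeric vector in `[0, 1]^m`.
#' @param data Normalized training [tabular_dataset()].
#' @param config A [cboa_config()].
#' @param folds Optional list of fixed fold assignments, one per repeat
#'   (defaults to stratified folds derived from `config$seed`).
#' @return The scalar objective `J`.
#' @export
evaluate_fitness <- function(position, data, config, folds = NULL) {
  mask <- binarize_position(position, config$threshold)
  if (is.null(folds)) folds <- fitness_folds(data$labels, config)
  acc <- mean(vapply(folds, function(f) {
    surrogate_cv_accuracy(data$features, data$labels, mask, f,
                          data$n_classes, config$lambda)
  }, 0))
  (1 - acc) + config$alpha * sum(mask) / length(mask)
}

# one stratified fold assignment per repeat, fixed for a whole optimizer run
fitness_folds <- function(labels, config) {
  lapply(seq_len(config$cv_repeats), function(r) {
    make_folds(labels, config$folds, config$seed + r - 1L)
  })
}

#' Candidate prey set
#'
#' The potential prey of bobcat `i` are the population members with strictly
#' better (smaller) objective: `CP_i = { k : F_k < F_i, k != i }`. The
#' incumbent best has an empty prey set.
#'
#' @param fitness Numeric fitness vector.
#' @param i Index of the hunting bobcat.
#' @return Integer vector of prey indices (possibly empty).
#' @export
candidate_prey_set <- function(fitness, i) {
  which(fitness < fitness[i] & seq_along(fitness) != i)
}

#' Exploration move toward a selected prey
#'
#' `x'_j = x_j + (1 - 2 r_j) (SP_j - I_j x_j)` with `r_j ~ U[0, 1]` and
#' `I_j` drawn equiprobably from \{1, 2\}; the result is clipped to bounds.
#' Draws come from the ambient RNG stream.
#'
#' @param position Current position.
#' @param prey Position of the selected prey.
#' @param lower,upper Bound vectors.
#' @param r,I Optional fixed draws (uniform factors and the 1/2
#'   multipliers), mainly for deterministic verification; drawn from the
#'   ambient RNG when `NULL`.
#' @return The moved, clipped position.
#' @export
exploration_step <- function(position, prey, lower = 0, upper = 1,
                             r = NULL, I = NULL) {
  m <- length(position)
  if (is.null(r)) r <- stats::runif(m)
  if (is.null(I)) I <- sample(1:2, m, replace = TRUE)
  out <- position + (1 - 2 * r) * (prey - I * position)
  pmin(pmax(out, lower), upper)
}

#' Exploitation (pursuit) move
#'
#' `x'_j = x_j + ((1 - 2 r_j) / (1 + t)) x_j`: a local perturbation whose
#' magnitude decays with the iteration counter `t`, clipped to bounds.
#'
#' @param position Current position.
#' @param t Iteration counter (1-based).
#' @param lower,upper Bound vectors.
#' @param r Optional fixed uniform draws for deterministic verification.
#' @return The moved, clipped position.
#' @export
exploitation_step <- function(position, t, lower = 0, upper = 1, r = NULL) {
  if (is.null(r)) r <- stats::runif(length(position))
  out <- position + (1 - 2 * r) / (1 + t) * position
  pmin(pmax(out, lower), upper)
}

#' Greedy acceptance
#'
#' Keep the candidate iff its objective does not exceed the incumbent's
#' (`new_F <= old_F`), which makes the best-so-far trace non-increasing.
#'
#' @param old_position,old_F Incumbent position and objective.
#' @param new_position,new_F Candidate position and objective.
#' @return List with the surviving `position` and `F`.
#' @export
greedy_accept <- function(old_position, old_F, new_position, new_F) {
  if (new_F <= old_F) {
    list(position = new_position, F = new_F)
  } else {
    list(position = old_position, F = old_F)
  }
}

#' Run CBOA wrapper feature selection
#'
#' Each iteration applies, per bobcat, an exploration move toward a randomly
#' chosen prey (skipped for the incumbent best, whose prey set is empty)
#' followed by an exploitation move, each under greedy acceptance. Fitness
#' values are cached per binarized subset, since many positions share a mask.
#'
#' @param data Normalized training [tabular_dataset()].
#' @param config A [cboa_config()].
#' @return A `cboa_result`: `best_position`, logical `best_mask`,
#'   `best_objective`, the per-iteration best-objective `trace`
#'   (non-increasing), and the number of distinct subset `evaluations`.
#' @export
run_cboa <- function(data, config = cboa_config()) {
  stopifnot(inherits(data, "tabular_dataset"))
  m <- ncol(data$features)
  lower <- rep(0, m)
  upper <- rep(1, m)
  folds <- fitness_folds(data$labels, config)
  cache <- new.env(parent = emptyenv())
  fit_of <- function(position) {
    mask <- binarize_position(position, config$threshold)
    key <- paste(which(mask), collapse = ",")
    if (is.null(cache[[key]])) {
      acc <- mean(vapply(folds, function(f) {
        surrogate_cv_accuracy(data$features, data$labels, mask, f,
                              data$n_classes, config$lambda)
      }, 0))
      cache[[key]] <- (1 - acc) + config$alpha * sum(mask) / m
    }
    cache[[key]]
  }
  X <- chaotic_init_population(lower, upper, config)
  with_local_seed(config$seed + 1L, {
    F <- apply(X, 1L, fit_of)
    best_i <- which.min(F)
    best_pos <- X[best_i, ]
    best_F <- F[best_i]
    trace <- numeric(config$max_iter)
    for (t in seq_len(config$max_iter)) {
      for (i in seq_len(config$n_pop)) {
        prey <- candidate_prey_set(F, i)
        if (length(prey) > 0L) {
          sp <- X[prey[sample.int(length(prey), 1L)], ]
          cand <- exploration_step(X[i, ], sp, lower, upper)
          kept <- greedy_accept(X[i, ], F[i], cand, fit_of(cand))
          X[i, ] <- kept$position
          F[i] <- kept$F
        }
        cand <- exploitation_step(X[i, ], t, lower, upper)
        kept <- greedy_accept(X[i, ], F[i], cand, fit_of(cand))
        X[i, ] <- kept$position
        F[i] <- kept$F
      }
      it_best <- which.min(F)
      if (F[it_best] <= best_F) {
        best_F <- F[it_best]
        best_pos <- X[it_best, ]
      }
      trace[t] <- best_F
    }
    structure(
      list(best_position = best_pos,
           best_mask = binarize_position(best_pos, config$threshold),
           best_objective = best_F, trace = trace,
           evaluations = length(ls(cache))),
      class = "cboa_result"
    )
  })
}

#' @export
print.cboa_result <- function(x, ...) {
  cat(sprintf("<cboa_result> %d/%d features selected, objective %.4f\n",
              sum(x$best_mask), length(x$best_mask), x$best_objective))
  invisible(x)
}

#' Exhaustive wrapper-objective search (oracle)
#'
#' Enumerates every non-empty feature subset and scores it with the same
#' fitness protocol as [run_cboa()]. Intended for small `m` as an
#' independent check of the metaheuristic.
#'
#' @param data Normalized training [tabular_dataset()].
#' @param config A [cboa_config()] (threshold unused).
#' @return List with `best_mask`, `best_objective` and the full `objectives`
#'   vector indexed by subset bit pattern.
#' @export
exhaustive_subset_search <- function(data, config = cboa_config()) {
  m <- ncol(data$features)
  if (m > 16L) stop("exhaustive search only supported for m <= 16", call. = FALSE)
  folds <- fitness_folds(data$labels, config)
  n_sub <- 2^m - 1L
  objectives <- numeric(n_sub)
  best <- Inf
  best_mask <- NULL
  for (code in seq_len(n_sub)) {
    mask <- as.logical(bitwAnd(code, 2^(seq_len(m) - 1L)))
    acc <- mean(vapply(folds, function(f) {
      surrogate_cv_accuracy(data$features, data$labels, mask, f,
                            data$n_classes, config$lambda)
    }, 0))
    J <- (1 - acc) + config$alpha * sum(mask) / m
    objectives[code] <- J
    if (J < best) {
      best <- J
      best_mask <- mask
    }
  }
  list(best_mask = best_mask, best_objective = best, objectives = objectives)
}
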