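#' Federated incremental learning configuration
#'
#' Defaults follow the standard federated setup for clinical tabular
#' streams: 5 local epochs, batch size 64, learning rate 1e-3 with heavy-ball
#' momentum 0.9, a bounded replay cache of `cache_size` samples per client,
#' and a personalized-informative-model (PIM) mixing parameter
#' `lambda` in (0, 1) whose pull toward the global model is
#' `q(lambda) = (1 - lambda) / (2 lambda)`.
#'
#' @param rounds Global communication rounds (default 200; the reference
#'   clinical runs use 500).
#' @param local_epochs Local epochs `E` per round (default 5).
#' @param batch_size Mini-batch size `B` (default 64).
#' @param lr Learning rate `eta` (default 0.001).
#' @param momentum Heavy-ball momentum (default 0.9), applied to both the
#'   PIM and the local update.
#' @param cache_size Replay cache capacity `M` per client.
#' @param lambda PIM mixing parameter in (0, 1); values near 1 emphasise
#'   local data, near 0 the global model. Default 0.5.
#' @param pim_iters PIM iteration budget `s`, which is also the importance
#'   accumulation horizon `S` (default 10).
#' @param seed Integer master seed.
#' @return A `fil_config` list.
#' @export
fil_config <- function(rounds = 200L, local_epochs = 5L, batch_size = 64L,
                       lr = 0.001, momentum = 0.9, cache_size = 50L,
                       lambda = 0.5, pim_iters = 10L, seed = 1L) {
  if (lambda <= 0 || lambda >= 1) {
    stop("`lambda` must lie strictly inside (0, 1)", call. = FALSE)
  }
  stopifnot(rounds >= 1L, local_epochs >= 1L, batch_size >= 1L, lr >= 0,
            cache_size >= 1L, pim_iters >= 1L)
  structure(
    list(rounds = as.integer(rounds), local_epochs = as.integer(local_epochs),
         batch_size = as.integer(batch_size), lr = lr, momentum = momentum,
         cache_size = as.integer(cache_size), lambda = lambda,
         pim_iters = as.integer(pim_iters), seed = as.integer(seed)),
    class = "fil_config"
  )
}

#' PIM global-pull coefficient
#'
#' `q(lambda) = (1 - lambda) / (2 lambda)` for `lambda` in (0, 1): strictly
#' decreasing, diverging as `lambda -> 0` (pure global recovery) and
#' vanishing as `lambda -> 1` (pure local training).
#'
#' @param lambda Mixing parameter in (0, 1).
#' @return The scalar coefficient.
#' @export
mixing_coefficient <- function(lambda) {
  if (any(lambda <= 0 | lambda >= 1)) {
    stop("`lambda` must lie strictly inside (0, 1)", call. = FALSE)
  }
  (1 - lambda) / (2 * lambda)
}

#' Squared gradient norm of one sample under the PIM
#'
#' `G = || grad of the sample's cross-entropy loss at the PIM parameters ||^2`.
#'
#' @param theta PIM parameter vector.
#' @param x Feature vector of the sample.
#' @param y Integer label.
#' @param n_classes Number of classes.
#' @return Nonnegative scalar.
#' @export
sample_gradient_norm <- function(theta, x, y, n_classes) {
  per_sample_grad_sqnorms(theta, matrix(x, nrow = 1L), y, n_classes)[1L]
}

#' Accumulate gradient norms into a sample-importance score
#'
#' `I = sum_{p=1..S} (1/p) G^p`: the harmonic weighting emphasises the early
#' PIM iterations, where the gradient signal reflects how much a sample
#' would still move the jointly-informed model.
#'
#' @param norm_history Numeric vector `G^1..G^S` of per-iteration squared
#'   gradient norms for one sample.
#' @return The scalar importance score.
#' @export
accumulate_importance <- function(norm_history) {
  if (length(norm_history) < 1L) stop("empty history", call. = FALSE)
  sum(norm_history / seq_along(norm_history))
}

#' Update the personalized informative model
#'
#' Runs `s` iterations of
#' `v <- v - eta * ( sum_i grad l(f_v(x_i), y_i) + q(lambda) (v - w) )`
#' with heavy-ball momentum, where the sum runs over the cached samples and
#' `w` is the received global model. The squared gradient norm of every
#' sample is recorded at each iteration for importance scoring.
#'
#' @param pim PIM parameter vector `v` (same layout as the global model).
#' @param global Global model parameter vector `w`.
#' @param X,y Cached samples (features matrix, integer labels).
#' @param n_classes Number of classes.
#' @param config A [fil_config()].
#' @return List with the updated `pim` and the `norms` matrix
#'   (`pim_iters` rows, one column per sample).
#' @export
pim_update <- function(pim, global, X, y, n_classes, config) {
  if (nrow(X) == 0L) stop("no cached samples to score", call. = FALSE)
  q <- mixing_coefficient(config$lambda)
  norms <- matrix(0, config$pim_iters, nrow(X))
  vel <- numeric(length(pim))
  for (p in seq_len(config$pim_iters)) {
    norms[p, ] <- per_sample_grad_sqnorms(pim, X, y, n_classes)
    g <- linear_grad(pim, X, y, n_classes, reduce = "sum") + q * (pim - global)
    vel <- config$momentum * vel - config$lr * g
    pim <- pim + vel
  }
  list(pim = pim, norms = norms)
}

#' Select the replay cache by importance
#'
#' Keeps the top-`M` candidates by importance score; ties at the cut are
#' broken toward the more recent sample (larger index), then by index.
#'
#' @param importance Numeric score vector, one entry per candidate in
#'   arrival order.
#' @param M Cache capacity.
#' @return Integer indices of the kept candidates, in arrival order.
#' @export
select_cache <- function(importance, M) {
  if (M < 1L) stop("cache capacity must be >= 1", call. = FALSE)
  keep <- order(importance, seq_along(importance),
                decreasing = c(TRUE, TRUE), method = "radix")
  sort(keep[seq_len(min(M, length(importance)))])
}

#' Local client training
#'
#' `E` epochs of mini-batch gradient descent with heavy-ball momentum on the
#' cross-entropy loss over the client's merged data (current task plus
#' replay cache), starting from the received global model.
#'
#' @param theta Starting parameter vector (the received global model).
#' @param X,y Training samples.
#' @param n_classes Number of classes.
#' @param config A [fil_config()].
#' @param seed Integer seed for the batch order.
#' @return The updated local parameter vector.
#' @export
local_train <- function(theta, X, y, n_classes, config, seed = config$seed) {
  n <- nrow(X)
  vel <- numeric(length(theta))
  with_local_seed(seed, {
    for (ep in seq_len(config$local_epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        g <- linear_grad(theta, X[idx, , drop = FALSE], y[idx], n_classes,
                         reduce = "mean")
        vel <- config$momentum * vel - config$lr * g
        theta <- theta + vel
      }
    }
    theta
  })
}

# one client's mutable state
client_state <- function(id, n_features, n_classes) {
  list(id = id,
       local = linear_model_init(n_features, n_classes),
       pim = linear_model_init(n_features, n_classes),
       cache_X = matrix(numeric(0), 0L, n_features),
       cache_y = integer(0),
       cache_importance = numeric(0),
       task_X = NULL, task_y = NULL)
}

# deliver task data to a client and refresh its replay cache: the PIM is
# updated on the previous holdings (previous task data plus existing cache;
# on the first task, the incoming data itself), every candidate is scored by
# accumulated gradient norm, and the top-M are cached
client_receive_task <- function(client, global, X, y, n_classes, config,
                                selection = c("importance", "random"),
                                seed = config$seed) {
  selection <- match.arg(selection)
  first_task <- is.null(client$task_X)
  cand_X <- rbind(if (!first_task) client$task_X, client$cache_X,
                  if (first_task) X)
  cand_y <- c(if (!first_task) client$task_y, client$cache_y,
              if (first_task) y)
  client$pim <- global
  upd <- pim_update(client$pim, global, cand_X, cand_y, n_classes, config)
  client$pim <- upd$pim
  imp <- apply(upd$norms, 2L, accumulate_importance)
  keep <- if (selection == "importance") {
    select_cache(imp, config$cache_size)
  } else {
    with_local_seed(seed, sort(sample.int(
      length(cand_y), min(config$cache_size, length(cand_y)))))
  }
  client$cache_X <- cand_X[keep, , drop = FALSE]
  client$cache_y <- cand_y[keep]
  client$cache_importance <- imp[keep]
  client$task_X <- X
  client$task_y <- y
  client
}

# merged training set for local updates: current task plus replay cache
client_train_data <- function(client) {
  list(X = rbind(client$task_X, client$cache_X),
       y = c(client$task_y, client$cache_y))
}

#' Run one global federated round
#'
#' Each participating client receives the global model, trains locally on
#' its merged data, and submits an update; updates are optionally clipped
#' and privatized, filtered for aberrance, weighted and averaged. If every
#' update is filtered out the round aborts and the previous global model is
#' retained.
#'
#' @param clients List of client states (see [run_experiment()] for the
#'   full orchestration that also handles task arrival and caching).
#' @param global Current global parameter vector.
#' @param n_classes Number of classes.
#' @param config A [fil_config()].
#' @param privacy Optional [privacy_config()] applied to every update.
#' @param filter_c Median/MAD filter multiplier (`NULL` disables filtering).
#' @param attack Optional [attack_config()] injected on the updates.
#' @param val_X,val_y Server validation split for update accuracies.
#' @param seed Integer seed.
#' @return List with the new `global` vector, the updated `clients`, the
#'   `updates` actually aggregated, the filter `kept`/`excluded` ids, and
#'   `aborted` (TRUE when the previous global was retained).
#' @export
global_round <- function(clients, global, n_classes, config,
                         privacy = NULL, filter_c = 3, attack = NULL,
                         val_X = NULL, val_y = NULL, seed = config$seed) {
  stopifnot(length(clients) >= 1L)
  seeds <- derive_seeds(seed, 2L * length(clients) + 1L)
  updates <- vector("list", length(clients))
  for (k in seq_along(clients)) {
    cl <- clients[[k]]
    td <- client_train_data(cl)
    theta <- local_train(global, td$X, td$y, n_classes, config, seeds[k])
    clients[[k]]$local <- theta
    acc <- if (!is.null(val_X)) {
      mean(linear_predict(theta, val_X, n_classes) == val_y)
    } else NA_real_
    attribution <- attribution_vector(theta, td$X, td$y, n_classes)
    updates[[k]] <- client_update(cl$id, theta, nrow(td$X), acc, attribution)
  }
  if (!is.null(attack)) {
    updates <- apply_attack(updates, attack, filter_c = filter_c,
                            seed = seeds[2L * length(clients) + 1L])
  }
  if (!is.null(privacy)) {
    # clip and privatize the per-round delta from the received global model,
    # not the full parameter vector, so the mechanism's sensitivity matches
    # what a round actually transmits
    ldp_seeds <- seeds[length(clients) + seq_along(updates)]
    if (length(updates) > length(clients)) {  # sybil replicas need seeds too
      ldp_seeds <- derive_seeds(seeds[length(clients) + 1L], length(updates))
    }
    updates <- lapply(seq_along(updates), function(k) {
      u <- updates[[k]]
      u$params <- u$params - global
      u <- clip_update(u, privacy$clip)
      u <- ldp_perturb(u, privacy, seed = ldp_seeds[k])
      u$params <- u$params + global
      u
    })
  }
  if (!is.null(filter_c)) {
    part <- robust_filter(updates, filter_c)
    kept <- part$kept
  } else {
    kept <- updates
    part <- list(kept = updates, excluded = list())
  }
  if (length(kept) == 0L) {
    return(list(global = global, clients = clients, updates = updates,
                kept = character(0),
                excluded = vapply(part$excluded, `[[`, "", "id"),
                aborted = TRUE))
  }
  w <- xai_weights(kept)
  new_global <- aggregate_updates(kept, w)
  list(global = new_global, clients = clients, updates = updates,
       kept = vapply(kept, `[[`, "", "id"),
       excluded = vapply(part$excluded, `[[`, "", "id"),
       aborted = FALSE)
}
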