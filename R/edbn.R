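# Entropy deep belief network: a stack of binary restricted Boltzmann
# machines whose hidden-layer widths are constrained by the information
# entropy of their visible layer, trained layer-wise by contrastive
# divergence, then unrolled into a feed-forward classifier and fine-tuned
# on cross-entropy. Min-max-normalized features in [0, 1] are treated as
# Bernoulli activation probabilities at the first visible layer.

PROB_CLIP <- 1e-6

#' Information entropy of a layer of binary units
#'
#' Per-node activation probabilities `p_i(1)` are the column means of the
#' activation matrix; the layer entropy is
#' `H = sum_i [ p_i(0) log2(1/p_i(0)) + p_i(1) log2(1/p_i(1)) ]` in bits,
#' with probabilities clipped to `[1e-6, 1 - 1e-6]` before the logs. `H`
#' attains its maximum, the node count, exactly when every `p_i = 1/2`.
#'
#' @param activations Numeric matrix in `[0, 1]`, samples in rows.
#' @return List with `p1` (per-node activation probabilities, clipped) and
#'   `H` (layer entropy in bits).
#' @export
layer_entropy <- function(activations) {
  activations <- as.matrix(activations)
  if (nrow(activations) == 0L) stop("no samples", call. = FALSE)
  if (any(activations < 0 | activations > 1)) {
    stop("activations must lie in [0, 1]", call. = FALSE)
  }
  p1 <- pmin(pmax(colMeans(activations), PROB_CLIP), 1 - PROB_CLIP)
  p0 <- 1 - p1
  H <- sum(p0 * log2(1 / p0) + p1 * log2(1 / p1))
  list(p1 = p1, H = H)
}

#' Entropy bounds on a hidden layer's width
#'
#' The admissible width range is `H_vo <= N_hid <= N_vo`: at least the
#' (ceiling of the) visible layer's entropy so no information is lost, at
#' most the visible unit count. A near-constant layer with `H < 1` is
#' floored at width 1 so a layer always exists.
#'
#' @param visible_activations Activation matrix of the visible layer.
#' @return Integer vector `c(n_min, n_max)`.
#' @export
hidden_size_bounds <- function(visible_activations) {
  H <- layer_entropy(visible_activations)$H
  n_vo <- ncol(as.matrix(visible_activations))
  n_min <- max(1L, as.integer(ceiling(H - 1e-9)))
  c(n_min = min(n_min, n_vo), n_max = n_vo)
}

rbm_params <- function(W, a, b) {
  structure(list(W = W, a = a, b = b, type = "binary"), class = "rbm_params")
}

rbm_hidden_prob <- function(rbm, V) {
  sigmoid(sweep(V %*% rbm$W, 2L, rbm$b, "+"))
}

rbm_visible_prob <- function(rbm, H) {
  sigmoid(sweep(H %*% t(rbm$W), 2L, rbm$a, "+"))
}

#' Train a binary RBM by one-step contrastive divergence
#'
#' CD-1 with mini-batches: hidden units are sampled once for the negative
#' phase, reconstructions use mean-field probabilities. Weights start at
#' `N(0, 0.01^2)`, biases at zero.
#'
#' @param data Numeric matrix in `[0, 1]` (treated as Bernoulli
#'   probabilities), samples in rows.
#' @param width Hidden layer width.
#' @param epochs Training epochs (0 returns the untouched initialization).
#' @param lr Learning rate (default 0.05).
#' @param batch_size Mini-batch size (default 32).
#' @param seed Integer seed; training is deterministic under it.
#' @return An `rbm_params` object with the per-epoch mean reconstruction
#'   error in `attr(, "recon_trace")`.
#' @export
train_rbm_cd <- function(data, width, epochs = 20L, lr = 0.05,
                         batch_size = 32L, seed = 1L) {
  data <- as.matrix(data)
  n_vis <- ncol(data)
  n <- nrow(data)
  with_local_seed(seed, {
    rbm <- rbm_params(matrix(stats::rnorm(n_vis * width, sd = 0.01),
                             n_vis, width),
                      numeric(n_vis), numeric(width))
    trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        V0 <- data[idx, , drop = FALSE]
        nb <- nrow(V0)
        Ph0 <- rbm_hidden_prob(rbm, V0)
        Hs <- matrix(stats::rbinom(nb * width, 1L, Ph0), nb, width)
        V1 <- rbm_visible_prob(rbm, Hs)
        Ph1 <- rbm_hidden_prob(rbm, V1)
        rbm$W <- rbm$W + lr * (crossprod(V0, Ph0) - crossprod(V1, Ph1)) / nb
        rbm$a <- rbm$a + lr * colMeans(V0 - V1)
        rbm$b <- rbm$b + lr * colMeans(Ph0 - Ph1)
      }
      trace[ep] <- reconstruction_error(rbm, data)
    }
    attr(rbm, "recon_trace") <- trace
    rbm
  })
}

#' Mean-field reconstruction error of an RBM
#'
#' Mean squared difference between the data and its one-step mean-field
#' reconstruction `v -> p(h|v) -> p(v|h)`.
#'
#' @param rbm An `rbm_params` object.
#' @param data Matrix in `[0, 1]`, samples in rows.
#' @return Nonnegative scalar.
#' @export
reconstruction_error <- function(rbm, data) {
  data <- as.matrix(data)
  if (ncol(data) != nrow(rbm$W)) stop("shape mismatch", call. = FALSE)
  V1 <- rbm_visible_prob(rbm, rbm_hidden_prob(rbm, data))
  mean((data - V1)^2)
}

#' Sample-averaged RBM interaction loss
#'
#' `L = (1/T) sum_t [ sum_ij W_ij v_i(t) h_j(t) + sum_i a_i v_i(t) +
#' sum_j b_j h_j(t) ]`: the positive energy form averaged over samples,
#' reported as a diagnostic (it is not the training objective).
#'
#' @param rbm An `rbm_params` object.
#' @param visible,hidden Matched matrices of visible and hidden unit values,
#'   samples in rows.
#' @return Scalar loss.
#' @export
rbm_loss <- function(rbm, visible, hidden) {
  visible <- as.matrix(visible)
  hidden <- as.matrix(hidden)
  if (nrow(visible) != nrow(hidden)) stop("sample counts differ", call. = FALSE)
  if (ncol(visible) != nrow(rbm$W) || ncol(hidden) != ncol(rbm$W)) {
    stop("shape mismatch", call. = FALSE)
  }
  interaction <- sum((visible %*% rbm$W) * hidden)
  (interaction + sum(visible %*% rbm$a) + sum(hidden %*% rbm$b)) /
    nrow(visible)
}

#' Greedy entropy-constrained structure search
#'
#' For each layer in turn: compute the entropy bounds of the current visible
#' activations, drop infeasible grid widths, train one RBM per remaining
#' candidate, keep the width with the smallest held-out reconstruction
#' error, freeze it, and propagate mean-field hidden probabilities upward.
#' Stops at `depth` layers (default and maximum 3).
#'
#' @param data Matrix in `[0, 1]`, samples in rows.
#' @param grid Candidate hidden widths per layer: either one numeric vector
#'   reused for every layer or a list of length `depth`.
#' @param depth Number of stacked RBMs (<= `max_depth`).
#' @param max_depth Depth cap (default 3).
#' @param epochs CD epochs per candidate.
#' @param lr,batch_size Passed to [train_rbm_cd()].
#' @param holdout_fraction Fraction of rows held out to score candidates.
#' @param pad_grid When no grid width is feasible for a layer, fall back to
#'   the layer's upper bound (always feasible) instead of erroring; used by
#'   the experiment orchestrator where the visible width depends on
#'   upstream feature selection.
#' @param seed Integer seed.
#' @return An `edbn_model`: list of fitted `rbms`, the chosen `widths`, the
#'   per-layer entropy `bounds`, and `depth`.
#' @export
search_structure <- function(data, grid, depth = 3L, max_depth = 3L,
                             epochs = 15L, lr = 0.05, batch_size = 32L,
                             holdout_fraction = 0.2, pad_grid = FALSE,
                             seed = 1L) {
  data <- as.matrix(data)
  depth <- as.integer(depth)
  if (depth > max_depth) stop("depth exceeds `max_depth`", call. = FALSE)
  if (!is.list(grid)) grid <- rep(list(grid), depth)
  seeds <- derive_seeds(seed, depth * max(lengths(grid)) + 1L)
  n <- nrow(data)
  holdout <- with_local_seed(seeds[1L],
                             sample.int(n, max(1L, round(holdout_fraction * n))))
  rbms <- vector("list", depth)
  widths <- integer(depth)
  bounds <- vector("list", depth)
  V <- data
  si <- 1L
  for (k in seq_len(depth)) {
    bk <- hidden_size_bounds(V[-holdout, , drop = FALSE])
    bounds[[k]] <- bk
    feasible <- sort(unique(as.integer(grid[[k]])))
    feasible <- feasible[feasible >= bk["n_min"] & feasible <= bk["n_max"]]
    if (length(feasible) == 0L) {
      if (pad_grid) {
        feasible <- bk[["n_max"]]
      } else {
        stop(sprintf("no feasible width for layer %d (bounds %d..%d)",
                     k, bk["n_min"], bk["n_max"]), call. = FALSE)
      }
    }
    best_err <- Inf
    for (w in feasible) {
      si <- si + 1L
      cand <- train_rbm_cd(V[-holdout, , drop = FALSE], w, epochs, lr,
                           batch_size, seeds[si])
      err <- reconstruction_error(cand, V[holdout, , drop = FALSE])
      if (err < best_err) {
        best_err <- err
        rbms[[k]] <- cand
        widths[k] <- w
      }
    }
    V <- rbm_hidden_prob(rbms[[k]], V)
  }
  structure(list(rbms = rbms, widths = widths, bounds = bounds,
                 depth = depth, head = NULL),
            class = "edbn_model")
}

#' @export
print.edbn_model <- function(x, ...) {
  cat(sprintf("<edbn_model> depth %d, widths %s%s\n", x$depth,
              paste(x$widths, collapse = "-"),
              if (is.null(x$head)) " (not fine-tuned)" else " (fine-tuned)"))
  invisible(x)
}

edbn_forward <- function(model, X) {
  A <- list(X)
  for (k in seq_len(model$depth)) {
    A[[k + 1L]] <- rbm_hidden_prob(model$rbms[[k]], A[[k]])
  }
  A
}

#' Fine-tune the unrolled EDBN and predict
#'
#' Unrolls the RBM stack into a sigmoid feed-forward network, attaches a
#' softmax output layer, and trains the whole network by mini-batch gradient
#' descent with momentum on the cross-entropy loss.
#'
#' @param model An `edbn_model` from [search_structure()].
#' @param train,test [tabular_dataset()]s with features in `[0, 1]`.
#' @param epochs Fine-tuning epochs.
#' @param lr Learning rate.
#' @param momentum Heavy-ball momentum (default 0.9).
#' @param batch_size Mini-batch size.
#' @param seed Integer seed.
#' @return List with integer `predictions` on the test set, the
#'   `probabilities` matrix (rows sum to 1), the fine-tuned `model`, and the
#'   final training `loss`.
#' @export
finetune_and_predict <- function(model, train, test, epochs = 300L, lr = 0.5,
                                 momentum = 0.9, batch_size = 32L, seed = 1L) {
  stopifnot(inherits(model, "edbn_model"))
  C <- train$n_classes
  if (any(!test$labels %in% unique(train$labels))) {
    stop("test labels contain classes unseen in training", call. = FALSE)
  }
  X <- train$features
  y <- train$labels
  n <- nrow(X)
  D <- model$depth
  # layer weights: RBM couplings + hidden biases, then a zero-initialized head
  Ws <- lapply(model$rbms, function(r) r$W)
  bs <- lapply(model$rbms, function(r) r$b)
  Ws[[D + 1L]] <- matrix(0, model$widths[D], C)
  bs[[D + 1L]] <- numeric(C)
  vel_W <- lapply(Ws, function(w) w * 0)
  vel_b <- lapply(bs, function(b) b * 0)
  loss <- NA_real_
  with_local_seed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        A <- list(X[idx, , drop = FALSE])
        for (k in seq_len(D)) {
          A[[k + 1L]] <- sigmoid(sweep(A[[k]] %*% Ws[[k]], 2L, bs[[k]], "+"))
        }
        P <- softmax_rows(sweep(A[[D + 1L]] %*% Ws[[D + 1L]], 2L,
                                bs[[D + 1L]], "+"))
        nb <- length(idx)
        delta <- (P - one_hot(y[idx], C)) / nb
        for (k in (D + 1L):1L) {
          gW <- crossprod(A[[k]], delta)
          gb <- colSums(delta)
          if (k > 1L) {
            delta <- (delta %*% t(Ws[[k]])) * A[[k]] * (1 - A[[k]])
          }
          vel_W[[k]] <- momentum * vel_W[[k]] - lr * gW
          vel_b[[k]] <- momentum * vel_b[[k]] - lr * gb
          Ws[[k]] <- Ws[[k]] + vel_W[[k]]
          bs[[k]] <- bs[[k]] + vel_b[[k]]
        }
      }
    }
    A <- list(X)
    for (k in seq_len(D)) {
      A[[k + 1L]] <- sigmoid(sweep(A[[k]] %*% Ws[[k]], 2L, bs[[k]], "+"))
    }
    P <- softmax_rows(sweep(A[[D + 1L]] %*% Ws[[D + 1L]], 2L, bs[[D + 1L]], "+"))
    loss <- -mean(log(pmax(P[cbind(seq_len(n), y + 1L)], 1e-12)))
  })
  A <- list(test$features)
  for (k in seq_len(D)) {
    A[[k + 1L]] <- sigmoid(sweep(A[[k]] %*% Ws[[k]], 2L, bs[[k]], "+"))
  }
  P <- softmax_rows(sweep(A[[D + 1L]] %*% Ws[[D + 1L]], 2L, bs[[D + 1L]], "+"))
  model$head <- list(W = Ws[[D + 1L]], b = bs[[D + 1L]])
  model$finetuned <- list(Ws = Ws, bs = bs)
  list(predictions = max.col(P, ties.method = "first") - 1L,
       probabilities = P, model = model, loss = loss)
}

#' Serialize an EDBN model to JSON
#'
#' @param model An `edbn_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
edbn_to_json <- function(model, path) {
  payload <- list(
    depth = model$depth, widths = model$widths,
    rbms = lapply(model$rbms, function(r) {
      list(W = as.numeric(r$W), dim = dim(r$W), a = r$a, b = r$b)
    })
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load an EDBN model from JSON
#'
#' @param path File written by [edbn_to_json()].
#' @return An `edbn_model` (without a fine-tuned head).
#' @export
edbn_from_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  rbms <- lapply(seq_len(p$depth), function(k) {
    r <- if (is.data.frame(p$rbms)) lapply(p$rbms, `[[`, k) else p$rbms[[k]]
    rbm_params(matrix(unlist(r$W), r$dim[1], r$dim[2]),
               unlist(r$a), unlist(r$b))
  })
  structure(list(rbms = rbms, widths = as.integer(p$widths), bounds = NULL,
                 depth = as.integer(p$depth), head = NULL),
            class = "edbn_model")
}
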