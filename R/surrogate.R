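# Surrogate fitness classifier for wrapper feature selection: a ridge-
# regularized logistic model fitted by IRLS. Deterministic (no random
# initialization), cheap on the small candidate subsets the optimizer
# evaluates, and refit from scratch for every candidate so fitness values
# are comparable across subsets.

# binary ridge logistic via iteratively reweighted least squares;
# intercept unpenalized
ridge_logistic_fit <- function(X, y, lambda = 0.5, max_iter = 25L,
                               tol = 1e-8) {
  Xb <- add_intercept(X)
  p <- ncol(Xb)
  pen <- diag(rep(lambda, p))
  pen[p, p] <- 0
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(Xb %*% beta)
    mu <- sigmoid(eta)
    w <- pmax(mu * (1 - mu), 1e-6)
    z <- eta + (y - mu) / w
    A <- crossprod(Xb * w, Xb) + pen
    b_new <- drop(solve(A, crossprod(Xb * w, z)))
    if (max(abs(b_new - beta)) < tol) {
      beta <- b_new
      break
    }
    beta <- b_new
  }
  beta
}

ridge_logistic_predict <- function(beta, X) {
  as.integer(sigmoid(drop(add_intercept(X) %*% beta)) > 0.5)
}

# stratified fold assignment, fixed once per optimizer run so every
# candidate subset is scored under the same protocol
make_folds <- function(y, k, seed) {
  with_local_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      pool <- sample(which(y == cl))
      fold[pool] <- rep_len(seq_len(k), length(pool))
    }
    fold
  })
}

# cross-validated accuracy of the surrogate restricted to the masked columns
surrogate_cv_accuracy <- function(X, y, mask, fold, n_classes,
                                  lambda = 0.5) {
  Xs <- X[, mask, drop = FALSE]
  correct <- 0L
  for (f in sort(unique(fold))) {
    tr <- fold != f
    if (n_classes == 2L) {
      beta <- ridge_logistic_fit(Xs[tr, , drop = FALSE], y[tr], lambda)
      pred <- ridge_logistic_predict(beta, Xs[!tr, , drop = FALSE])
    } else {
      theta <- softmax_gd_fit(Xs[tr, , drop = FALSE], y[tr], n_classes,
                              lambda)
      pred <- linear_predict(theta, Xs[!tr, , drop = FALSE], n_classes)
    }
    correct <- correct + sum(pred == y[!tr])
  }
  correct / length(y)
}

# deterministic full-batch gradient-descent softmax fit (multiclass surrogate)
softmax_gd_fit <- function(X, y, n_classes, lambda = 0.5, iters = 150L,
                           lr = 0.5) {
  theta <- linear_model_init(ncol(X), n_classes)
  n <- nrow(X)
  for (it in seq_len(iters)) {
    g <- linear_grad(theta, X, y, n_classes, reduce = "mean") +
      (lambda / n) * theta
    theta <- theta - lr * g
  }
  theta
}
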