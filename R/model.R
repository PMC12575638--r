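# Linear softmax (multinomial logistic) base learner.
#
# The federated update rules are model-agnostic; a linear softmax keeps the
# inner personalized-model loop cheap while remaining a faithful gradient
# learner for cross-entropy loss. Parameters live in one flat vector of
# length (m + 1) * C -- per-class weight column then bias -- so client,
# personalized and global models all share a single parameter layout.

linear_model_init <- function(n_features, n_classes) {
  numeric((n_features + 1L) * n_classes)
}

param_matrix <- function(theta, n_features, n_classes) {
  matrix(theta, n_features + 1L, n_classes)
}

add_intercept <- function(X) cbind(X, 1)

one_hot <- function(y, n_classes) {
  Y <- matrix(0, length(y), n_classes)
  Y[cbind(seq_along(y), y + 1L)] <- 1
  Y
}

# class-probability matrix, rows sum to 1
linear_forward <- function(theta, X, n_classes) {
  Xb <- add_intercept(X)
  softmax_rows(Xb %*% param_matrix(theta, ncol(X), n_classes))
}

linear_predict <- function(theta, X, n_classes) {
  max.col(linear_forward(theta, X, n_classes), ties.method = "first") - 1L
}

# mean cross-entropy over samples
linear_loss <- function(theta, X, y, n_classes) {
  P <- linear_forward(theta, X, n_classes)
  p <- P[cbind(seq_along(y), y + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

# gradient of the cross-entropy over `X`; `reduce = "sum"` gives the plain
# sum over samples (the personalized-model update), "mean" the average
linear_grad <- function(theta, X, y, n_classes, reduce = c("mean", "sum")) {
  reduce <- match.arg(reduce)
  Xb <- add_intercept(X)
  P <- softmax_rows(Xb %*% param_matrix(theta, ncol(X), n_classes))
  R <- P - one_hot(y, n_classes)
  G <- crossprod(Xb, R)
  if (reduce == "mean") G <- G / nrow(X)
  as.numeric(G)
}

# squared gradient norm of each sample's own loss term: the per-sample
# gradient is the outer product xb (p - e_y)', so its squared Frobenius
# norm factorises as |xb|^2 * |p - e_y|^2
per_sample_grad_sqnorms <- function(theta, X, y, n_classes) {
  Xb <- add_intercept(X)
  P <- softmax_rows(Xb %*% param_matrix(theta, ncol(X), n_classes))
  R <- P - one_hot(y, n_classes)
  rowSums(Xb^2) * rowSums(R^2)
}
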