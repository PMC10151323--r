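# Dense-layer primitives and small helpers; the convolutional kernels,
# batch normalization and pooling live in src/kernels.cpp.

.dropout_forward <- function(X, rate, training) {
  if (!training || rate <= 0) return(list(out = X, mask = NULL))
  mask <- array(stats::runif(length(X)) >= rate, dim = dim(X)) / (1 - rate)
  list(out = X * mask, mask = mask)
}

.dense_forward <- function(X, W, b) {
  W %*% X + b
}

.dense_backward <- function(dY, X, W) {
  list(dX = crossprod(W, dY), dW = tcrossprod(dY, X), db = rowSums(dY))
}

.lrelu_forward <- function(X, slope) lrelu_fwd(X, slope)

.lrelu_backward <- function(dY, X, slope) lrelu_bwd(dY, X, slope)

# column-wise softmax of a (d x n) logit matrix, numerically shifted
.softmax_cols <- function(Z) {
  Z <- sweep(Z, 2, apply(Z, 2, max), "-")
  E <- exp(Z)
  sweep(E, 2, colSums(E), "/")
}

.he_init <- function(nrow_, ncol_, fan_in) {
  matrix(stats::rnorm(nrow_ * ncol_, 0, sqrt(2 / fan_in)), nrow_, ncol_)
}
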