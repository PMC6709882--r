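# Minimal neural-network engine: dense and 2D-convolution layers (im2col +
# BLAS gemm), non-overlapping max pooling, per-blob group max, softmax
# cross-entropy with L2 weight decay, and Adam. Analytic gradients are
# verified against numerical differentiation in the test suite.

# He-scaled initialization for a dense/conv weight block
nn_init_dense <- function(n_in, n_out) {
  list(W = matrix(rnorm(n_in * n_out) * sqrt(2 / n_in), n_in, n_out),
       b = rep(0, n_out))
}

# row-wise softmax
nn_softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# mean cross-entropy of probabilities against one-hot rows
nn_cross_entropy <- function(probs, onehot) {
  -mean(rowSums(onehot * log(pmax(probs, 1e-12))))
}

# one-hot rows in (positive, negative) order: positives are c(1, 0)
nn_onehot <- function(labels) {
  cbind(positive = as.numeric(labels == "positive"),
        negative = as.numeric(labels == "negative"))
}

# L2 penalty over weight matrices (biases excluded)
nn_l2_penalty <- function(params, l2) {
  if (l2 == 0) return(0)
  l2 / 2 * sum(vapply(params, function(p) sum(p$W^2), numeric(1)))
}

# Adam with bias correction; params/grads are parallel lists of (W, b) pairs
nn_adam_init <- function(params) {
  lapply(params, function(p) list(
    mW = p$W * 0, vW = p$W * 0, mb = p$b * 0, vb = p$b * 0))
}

nn_adam_step <- function(params, grads, state, lr, t,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(params)) {
    s <- state[[i]]
    s$mW <- beta1 * s$mW + (1 - beta1) * grads[[i]]$W
    s$vW <- beta2 * s$vW + (1 - beta2) * grads[[i]]$W^2
    s$mb <- beta1 * s$mb + (1 - beta1) * grads[[i]]$b
    s$vb <- beta2 * s$vb + (1 - beta2) * grads[[i]]$b^2
    c1 <- 1 - beta1^t
    c2 <- 1 - beta2^t
    params[[i]]$W <- params[[i]]$W - lr * (s$mW / c1) / (sqrt(s$vW / c2) + eps)
    params[[i]]$b <- params[[i]]$b - lr * (s$mb / c1) / (sqrt(s$vb / c2) + eps)
    state[[i]] <- s
  }
  list(params = params, state = state)
}

#' Training configuration for the neural classifiers
#'
#' Loss is softmax cross-entropy on the one-hot class pair (positives are
#' `[1, 0]`) plus an L2 weight penalty; optimization is Adam.
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam step size.
#' @param l2 L2 weight-decay coefficient.
#' @param seed RNG seed (initialization and shuffling); training is
#'   CPU-reproducible given it.
#' @param verbose print per-epoch progress.
#' @return an object of class `train_config`.
#' @export
train_config <- function(epochs = 30L, batch_size = 64L, lr = 1e-3,
                         l2 = 1e-4, seed = 1L, verbose = FALSE) {
  if (epochs < 1 || batch_size < 1 || lr <= 0 || l2 < 0)
    abort("invalid training configuration")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr = lr, l2 = l2, seed = as.integer(seed), verbose = verbose),
            class = "train_config")
}
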