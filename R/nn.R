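# Internal dense-network primitives. The architecture is fixed by the method:
# dense(n_features -> hidden1, ReLU) -> dropout -> dense(hidden1 -> hidden2,
# ReLU) -> dropout -> dense(hidden2 -> n_classes, softmax), trained with
# categorical cross-entropy and SGD with momentum. Dropout is "inverted"
# (activations scaled by 1/(1-p) at train time) so inference needs no
# rescaling.

# He-style uniform fan-in initialization, drawn from the current RNG stream.
nn_init <- function(n_features, hidden1, hidden2, n_classes) {
  he <- function(n_in, n_out) {
    lim <- sqrt(6 / n_in)
    matrix(runif(n_in * n_out, -lim, lim), nrow = n_in, ncol = n_out)
  }
  list(
    W1 = he(n_features, hidden1), b1 = numeric(hidden1),
    W2 = he(hidden1, hidden2),    b2 = numeric(hidden2),
    W3 = he(hidden2, n_classes),  b3 = numeric(n_classes)
  )
}

nn_zero_like <- function(w) lapply(w, function(m) m * 0)

# Row-wise softmax with max subtraction for numerical stability.
softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

add_bias <- function(m, b) m + rep(b, each = nrow(m))

# Inference-mode forward pass: X (cells x features) -> likelihoods
# (cells x classes). Dropout disabled.
nn_forward <- function(w, x) {
  h1 <- pmax(add_bias(x %*% w$W1, w$b1), 0)
  h2 <- pmax(add_bias(h1 %*% w$W2, w$b2), 0)
  softmax_rows(add_bias(h2 %*% w$W3, w$b3))
}

# Training-mode forward pass with dropout masks; returns intermediates
# needed for backprop.
nn_forward_train <- function(w, x, dropout_rate) {
  a1 <- add_bias(x %*% w$W1, w$b1)
  h1 <- pmax(a1, 0)
  m1 <- matrix(rbinom(length(h1), 1L, 1 - dropout_rate) / (1 - dropout_rate),
               nrow = nrow(h1))
  h1d <- h1 * m1
  a2 <- add_bias(h1d %*% w$W2, w$b2)
  h2 <- pmax(a2, 0)
  m2 <- matrix(rbinom(length(h2), 1L, 1 - dropout_rate) / (1 - dropout_rate),
               nrow = nrow(h2))
  h2d <- h2 * m2
  p <- softmax_rows(add_bias(h2d %*% w$W3, w$b3))
  list(a1 = a1, m1 = m1, h1d = h1d, a2 = a2, m2 = m2, h2d = h2d, p = p)
}

# Gradients of mean categorical cross-entropy for one minibatch.
# y_onehot: cells x classes.
nn_backward <- function(w, x, y_onehot, fw) {
  b <- nrow(x)
  dlogits <- (fw$p - y_onehot) / b
  dW3 <- crossprod(fw$h2d, dlogits)
  db3 <- colSums(dlogits)
  dh2d <- tcrossprod(dlogits, w$W3)
  da2 <- dh2d * fw$m2 * (fw$a2 > 0)
  dW2 <- crossprod(fw$h1d, da2)
  db2 <- colSums(da2)
  dh1d <- tcrossprod(da2, w$W2)
  da1 <- dh1d * fw$m1 * (fw$a1 > 0)
  dW1 <- crossprod(x, da1)
  db1 <- colSums(da1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, W3 = dW3, b3 = db3)
}

# One SGD-with-momentum update; returns updated weights and velocities.
nn_sgd_step <- function(w, v, g, lr, momentum) {
  for (nm in names(w)) {
    v[[nm]] <- momentum * v[[nm]] - lr * g[[nm]]
    w[[nm]] <- w[[nm]] + v[[nm]]
  }
  list(w = w, v = v)
}

nn_cross_entropy <- function(p, y_idx) {
  -mean(log(pmax(p[cbind(seq_len(nrow(p)), y_idx)], 1e-12)))
}

nn_accuracy <- function(p, y_idx) {
  mean(max.col(p, ties.method = "first") == y_idx)
}

nn_param_count <- function(w) sum(vapply(w, length, integer(1)))
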