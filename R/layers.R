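# R-side layer algebra for the conv-net engine. Convolutions, transposed
# convolutions and max-pooling are compiled (src/conv_ops.cpp); batch norm,
# ReLU, dropout, softmax and the segmentation losses live here. Tensors are
# [H, W, C, N] double arrays.

as_tensor <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  stopifnot(length(dim(x)) == 4L)
  x
}

channel_stat <- function(x, f) {
  C <- dim(x)[3]
  m <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)
  f(m)
}

relu_fw <- function(z) .relu_forward(z)
relu_bw <- function(dz, z) .relu_backward(dz, z)

ch_concat <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

# batch norm, fused via the per-channel C++ helpers; the backward pass
# reconstructs every xhat-dependent sum from raw sums of x and dy, so the
# normalized tensor is never materialised.
bn_fw <- function(x, gamma, beta, state, training, momentum = 0.9,
                  eps = 1e-5) {
  m <- prod(dim(x)[c(1, 2, 4)])
  if (training) {
    cs <- .channel_sums(x)
    mu <- cs[, 1] / m
    v <- cs[, 2] / m - mu^2
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * v
  } else {
    mu <- state$mean
    v <- state$var
  }
  invstd <- 1 / sqrt(v + eps)
  a <- gamma * invstd
  y <- .channel_affine(x, a, beta - mu * a)
  list(y = y, cache = list(x = x, mu = mu, invstd = invstd), state = state)
}

bn_bw <- function(dy, cache, gamma) {
  m <- prod(dim(dy)[c(1, 2, 4)])
  invstd <- cache$invstd; mu <- cache$mu
  s1 <- .channel_sums(dy)[, 1]                      # sum dy per channel
  sxy <- .channel_dot(dy, cache$x)                  # sum dy * x
  s2 <- invstd * (sxy - mu * s1)                    # sum dy * xhat
  dgamma <- s2
  dbeta <- s1
  # dx = invstd*gamma*(dy - s1/m - xhat*s2/m), xhat = invstd*(x - mu)
  A <- invstd * gamma
  B <- -invstd * A * s2 / m
  D <- -A * s1 / m - B * mu
  dx <- .channel_affine(dy, A, D, cache$x, B)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

dropout_fw <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(y = x, mask = NULL))
  mask <- array((runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(y = x * mask, mask = mask)
}

softmax_channels <- function(z) {
  zmax <- pmax(z[, , 1, , drop = FALSE], z[, , 2, , drop = FALSE])
  e1 <- exp(z[, , 1, , drop = FALSE] - zmax)
  e2 <- exp(z[, , 2, , drop = FALSE] - zmax)
  s <- e1 + e2
  out <- z
  out[, , 1, ] <- e1 / s
  out[, , 2, ] <- e2 / s
  out
}

# target: [H, W, N] with values 0 (BG), 1 (FG), 2 (ignore). Returns the mean
# weighted cross-entropy over counted (non-ignore) pixels and the gradient
# with respect to the logits; ignore pixels get exactly zero gradient.
seg_loss_grad <- function(probs, target, weights, grad = TRUE) {
  d <- dim(probs)
  target <- array(target, d[c(1, 2, 4)])
  counted <- target != TRIMAP_IGNORE
  n_count <- sum(counted)
  if (n_count == 0) abort_input("all pixels are ignore: loss is undefined")
  p0 <- array(probs[, , 1, ], d[c(1, 2, 4)])
  p1 <- array(probs[, , 2, ], d[c(1, 2, 4)])
  is_fg <- target == TRIMAP_FG
  p_true <- ifelse(is_fg, p1, p0)
  w_map <- ifelse(is_fg, weights[1], weights[2]) * counted
  loss <- sum(w_map * -log(pmax(p_true, 1e-12))) / n_count
  if (!grad) return(list(loss = loss))
  dlogits <- array(0, d)
  dlogits[, , 1, ] <- (p0 - !is_fg) * w_map / n_count
  dlogits[, , 2, ] <- (p1 - is_fg) * w_map / n_count
  list(loss = loss, dlogits = dlogits)
}
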