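# Minimal dense-tensor neural-net primitives for the small segmentation and
# regression networks. Tensors are base-R arrays [H, W, C, N]; convolutions
# run through the compiled im2col kernels; everything else is vectorized R.
# All functions are pure: parameters in, parameters out.

nn_conv3 <- function(x, W, b) .conv3_fwd(x, W, b)
nn_conv3_bwd <- function(x, W, dy) .conv3_bwd(x, W, dy)

# 1x1 convolution: channel mixing per pixel. W is C x O, b length O.
nn_conv1 <- function(x, W, b) {
  d <- dim(x); H <- d[1]; W_ <- d[2]; C <- d[3]; N <- d[4]
  y <- array(0, c(H, W_, ncol(W), N))
  xm <- matrix(x, nrow = H * W_)
  for (n in seq_len(N)) {
    cols <- ((n - 1L) * C + 1L):(n * C)
    y[, , , n] <- array(xm[, cols, drop = FALSE] %*% W +
                          rep(b, each = H * W_),
                        c(H, W_, ncol(W)))
  }
  y
}

nn_conv1_bwd <- function(x, W, dy) {
  d <- dim(x); H <- d[1]; W_ <- d[2]; C <- d[3]; N <- d[4]
  O <- ncol(W)
  dx <- array(0, d)
  dW <- matrix(0, C, O)
  db <- numeric(O)
  xm <- matrix(x, nrow = H * W_)
  dym <- matrix(dy, nrow = H * W_)
  for (n in seq_len(N)) {
    xc <- ((n - 1L) * C + 1L):(n * C)
    oc <- ((n - 1L) * O + 1L):(n * O)
    dyn <- dym[, oc, drop = FALSE]
    dW <- dW + t(xm[, xc, drop = FALSE]) %*% dyn
    db <- db + colSums(dyn)
    dx[, , , n] <- array(dyn %*% t(W), c(H, W_, C))
  }
  list(dx = dx, dW = dW, db = db)
}

nn_relu <- function(x) x * (x > 0)
nn_relu_bwd <- function(x, dy) dy * (x > 0)

# 2x2 average pooling (H, W must be even).
nn_pool2 <- function(x) {
  d <- dim(x)
  o1 <- seq(1L, d[1], 2L); e1 <- o1 + 1L
  o2 <- seq(1L, d[2], 2L); e2 <- o2 + 1L
  (x[o1, o2, , , drop = FALSE] + x[e1, o2, , , drop = FALSE] +
   x[o1, e2, , , drop = FALSE] + x[e1, e2, , , drop = FALSE]) / 4
}

nn_pool2_bwd <- function(dy, in_dim) {
  dx <- array(0, in_dim)
  o1 <- seq(1L, in_dim[1], 2L); e1 <- o1 + 1L
  o2 <- seq(1L, in_dim[2], 2L); e2 <- o2 + 1L
  q <- dy / 4
  dx[o1, o2, , ] <- q; dx[e1, o2, , ] <- q
  dx[o1, e2, , ] <- q; dx[e1, e2, , ] <- q
  dx
}

# Nearest-neighbour 2x upsampling; its adjoint is summing each 2x2 block.
nn_up2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

nn_up2_bwd <- function(dy) nn_pool2(dy) * 4

# Batch normalization over (H, W, N) per channel.
#   mode "train": batch statistics, running stats updated (returned).
#   mode "eval":  stored running statistics.
#   mode "tta":   statistics of each input alone (per sample, per channel) —
#                 the test-time adaptation used for domain-shifted images.
nn_bn <- function(x, gamma, beta, running, mode, momentum = 0.1, eps = 1e-8) {
  d <- dim(x); P <- d[1] * d[2]; C <- d[3]; N <- d[4]
  xm <- matrix(x, nrow = P)   # columns indexed by (c, n): col = (n-1)*C + c
  cidx <- rep(seq_len(C), N)
  if (mode == "train") {
    mu_cn <- colMeans(xm)
    mu <- as.numeric(rowsum(mu_cn, cidx)) / N
    cent <- xm - rep(mu[cidx], each = P)
    v_cn <- colMeans(cent^2)
    v <- as.numeric(rowsum(v_cn, cidx)) / N
    inv_sd <- 1 / sqrt(v + eps)
    xhat <- cent * rep(inv_sd[cidx], each = P)
    y <- xhat * rep(gamma[cidx], each = P) + rep(beta[cidx], each = P)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
    list(y = array(y, d), running = running,
         cache = list(xhat = xhat, inv_sd = inv_sd, cidx = cidx, d = d,
                      cent = cent))
  } else if (mode == "eval") {
    inv_sd <- 1 / sqrt(running$var + eps)
    y <- (xm - rep(running$mean[cidx], each = P)) * rep(inv_sd[cidx], each = P)
    y <- y * rep(gamma[cidx], each = P) + rep(beta[cidx], each = P)
    list(y = array(y, d), running = running, cache = NULL)
  } else if (mode == "tta") {
    mu_cn <- colMeans(xm)
    cent <- xm - rep(mu_cn, each = P)
    v_cn <- colMeans(cent^2)
    y <- cent / rep(sqrt(v_cn + eps), each = P)
    y <- y * rep(gamma[cidx], each = P) + rep(beta[cidx], each = P)
    list(y = array(y, d), running = running, cache = NULL)
  } else {
    stop_sgp("invalid_input", sprintf("unknown BN mode `%s`", mode))
  }
}

# Backward for training-mode batch norm.
nn_bn_bwd <- function(dy, gamma, cache) {
  d <- cache$d; P <- d[1] * d[2]; C <- d[3]; N <- d[4]
  m <- P * N
  cidx <- cache$cidx
  dym <- matrix(dy, nrow = P)
  dxhat <- dym * rep(gamma[cidx], each = P)
  dgamma <- as.numeric(rowsum(colSums(dym * cache$xhat), cidx))
  dbeta <- as.numeric(rowsum(colSums(dym), cidx))
  sum_dxhat <- as.numeric(rowsum(colSums(dxhat), cidx))
  sum_dxhat_xhat <- as.numeric(rowsum(colSums(dxhat * cache$xhat), cidx))
  inv_sd <- cache$inv_sd
  dx <- (dxhat - rep(sum_dxhat[cidx] / m, each = P) -
         cache$xhat * rep(sum_dxhat_xhat[cidx] / m, each = P)) *
        rep(inv_sd[cidx], each = P)
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# He-normal initialization for a 3x3 conv with C_in input channels.
init_conv3 <- function(c_in, c_out) {
  fan_in <- c_in * 9
  list(W = matrix(stats::rnorm(fan_in * c_out, 0, sqrt(2 / fan_in)),
                  fan_in, c_out),
       b = numeric(c_out))
}

init_bn <- function(c_out) {
  list(gamma = rep(1, c_out), beta = numeric(c_out),
       running = list(mean = numeric(c_out), var = rep(1, c_out)))
}

# Adam update; params/grads are flat named lists of numeric arrays.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gr <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gr
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gr^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Numerically stable (optionally pixel-weighted) mean sigmoid cross-entropy
# and its gradient.
bce_loss <- function(logits, targets, weights = NULL) {
  l <- pmax(logits, 0) - logits * targets + log1p(exp(-abs(logits)))
  if (!is.null(weights)) l <- l * weights
  mean(l)
}

bce_grad <- function(logits, targets, weights = NULL) {
  g <- sigmoid(logits) - targets
  if (!is.null(weights)) g <- g * weights
  g / length(logits)
}
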