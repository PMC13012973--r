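# Small encoder-decoder segmentation network ("U-Net at desk scale"):
# two 3x3 conv + BN + ReLU blocks at full resolution, one at half resolution,
# a skip concatenation, one decoder block and a 1x1 output head with three
# sigmoid channels (shortbones, carpals, wrist). Every batch-norm directly
# follows a linear convolution, so per-input statistics (TTA mode) make the
# thresholded output exactly invariant to positive affine intensity
# transforms of the input.

segnet_init <- function(c1 = 8L, c2 = 16L) {
  k1 <- init_conv3(1L, c1); k2 <- init_conv3(c1, c1)
  k3 <- init_conv3(c1, c2); k4 <- init_conv3(c1 + c2, c1)
  params <- list(
    w1 = k1$W, b1 = k1$b, g1 = rep(1, c1), be1 = numeric(c1),
    w2 = k2$W, b2 = k2$b, g2 = rep(1, c1), be2 = numeric(c1),
    w3 = k3$W, b3 = k3$b, g3 = rep(1, c2), be3 = numeric(c2),
    w4 = k4$W, b4 = k4$b, g4 = rep(1, c1), be4 = numeric(c1),
    w5 = matrix(stats::rnorm(c1 * 3, 0, sqrt(2 / c1)), c1, 3), b5 = numeric(3)
  )
  running <- list(bn1 = init_bn(c1)$running, bn2 = init_bn(c1)$running,
                  bn3 = init_bn(c2)$running, bn4 = init_bn(c1)$running)
  list(params = params, running = running, c1 = c1, c2 = c2)
}

segnet_forward <- function(params, running, x, mode) {
  c1 <- length(params$g1); c2 <- length(params$g3)
  z1 <- nn_conv3(x, params$w1, params$b1)
  b1 <- nn_bn(z1, params$g1, params$be1, running$bn1, mode)
  a1 <- nn_relu(b1$y)
  z2 <- nn_conv3(a1, params$w2, params$b2)
  b2 <- nn_bn(z2, params$g2, params$be2, running$bn2, mode)
  a2 <- nn_relu(b2$y)
  p <- nn_pool2(a2)
  z3 <- nn_conv3(p, params$w3, params$b3)
  b3 <- nn_bn(z3, params$g3, params$be3, running$bn3, mode)
  a3 <- nn_relu(b3$y)
  u <- nn_up2(a3)
  d <- dim(a2)
  cat4 <- array(0, c(d[1], d[2], c1 + c2, d[4]))
  cat4[, , seq_len(c1), ] <- a2
  cat4[, , c1 + seq_len(c2), ] <- u
  z4 <- nn_conv3(cat4, params$w4, params$b4)
  b4 <- nn_bn(z4, params$g4, params$be4, running$bn4, mode)
  a4 <- nn_relu(b4$y)
  logits <- nn_conv1(a4, params$w5, params$b5)
  if (mode == "train") {
    running <- list(bn1 = b1$running, bn2 = b2$running, bn3 = b3$running,
                    bn4 = b4$running)
  }
  list(logits = logits, running = running,
       cache = list(x = x, z1 = z1, b1 = b1, a1 = a1, z2 = z2, b2 = b2,
                    a2 = a2, p = p, z3 = z3, b3 = b3, a3 = a3, u = u,
                    cat4 = cat4, z4 = z4, b4 = b4, a4 = a4))
}

segnet_backward <- function(params, cache, dlogits) {
  c1 <- length(params$g1); c2 <- length(params$g3)
  g5 <- nn_conv1_bwd(cache$a4, params$w5, dlogits)
  da4 <- nn_relu_bwd(cache$b4$y, g5$dx)
  g4bn <- nn_bn_bwd(da4, params$g4, cache$b4$cache)
  g4 <- nn_conv3_bwd(cache$cat4, params$w4, g4bn$dx)
  dcat <- g4$dx
  da2 <- dcat[, , seq_len(c1), , drop = FALSE]
  du <- dcat[, , c1 + seq_len(c2), , drop = FALSE]
  da3 <- nn_up2_bwd(du)
  da3 <- nn_relu_bwd(cache$b3$y, da3)
  g3bn <- nn_bn_bwd(da3, params$g3, cache$b3$cache)
  g3 <- nn_conv3_bwd(cache$p, params$w3, g3bn$dx)
  da2 <- da2 + nn_pool2_bwd(g3$dx, dim(cache$a2))
  da2 <- nn_relu_bwd(cache$b2$y, da2)
  g2bn <- nn_bn_bwd(da2, params$g2, cache$b2$cache)
  g2 <- nn_conv3_bwd(cache$a1, params$w2, g2bn$dx)
  da1 <- nn_relu_bwd(cache$b1$y, g2$dx)
  g1bn <- nn_bn_bwd(da1, params$g1, cache$b1$cache)
  g1 <- nn_conv3_bwd(cache$x, params$w1, g1bn$dx)
  list(w1 = g1$dW, b1 = g1$db, g1 = g1bn$dgamma, be1 = g1bn$dbeta,
       w2 = g2$dW, b2 = g2$db, g2 = g2bn$dgamma, be2 = g2bn$dbeta,
       w3 = g3$dW, b3 = g3$db, g3 = g3bn$dgamma, be3 = g3bn$dbeta,
       w4 = g4$dW, b4 = g4$db, g4 = g4bn$dgamma, be4 = g4bn$dbeta,
       w5 = g5$dW, b5 = g5$db)
}
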