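# Small convolutional age regressor: four 3x3 conv + ReLU + 2x2 average-pool
# blocks, global average pooling and a linear head mapping 32 features to a
# single age in months. No normalization layers: the input is standardized
# with scalar source-domain statistics stored in the model state, and the
# linear head makes frozen-backbone fine-tuning a plain least-squares refit.

regnet_channels <- c(8L, 16L, 16L, 32L)

regnet_init <- function() {
  ch <- regnet_channels
  k1 <- init_conv3(1L, ch[1]); k2 <- init_conv3(ch[1], ch[2])
  k3 <- init_conv3(ch[2], ch[3]); k4 <- init_conv3(ch[3], ch[4])
  list(w1 = k1$W, b1 = k1$b, w2 = k2$W, b2 = k2$b,
       w3 = k3$W, b3 = k3$b, w4 = k4$W, b4 = k4$b,
       wh = stats::rnorm(ch[4], 0, sqrt(1 / ch[4])), bh = 0)
}

regnet_features <- function(params, x, want_cache = FALSE) {
  z1 <- nn_conv3(x, params$w1, params$b1); a1 <- nn_relu(z1); p1 <- nn_pool2(a1)
  z2 <- nn_conv3(p1, params$w2, params$b2); a2 <- nn_relu(z2); p2 <- nn_pool2(a2)
  z3 <- nn_conv3(p2, params$w3, params$b3); a3 <- nn_relu(z3); p3 <- nn_pool2(a3)
  z4 <- nn_conv3(p3, params$w4, params$b4); a4 <- nn_relu(z4); p4 <- nn_pool2(a4)
  d <- dim(p4)
  feats <- t(colMeans(matrix(p4, nrow = d[1] * d[2])))  # 1 x (C*N)
  feats <- matrix(feats, nrow = d[4], ncol = d[3], byrow = TRUE)  # N x C
  out <- list(feats = feats)
  if (want_cache) {
    out$cache <- list(x = x, z1 = z1, a1 = a1, p1 = p1, z2 = z2, a2 = a2,
                      p2 = p2, z3 = z3, a3 = a3, p3 = p3, z4 = z4, a4 = a4,
                      p4 = p4)
  }
  out
}

regnet_forward <- function(params, x, want_cache = FALSE) {
  f <- regnet_features(params, x, want_cache)
  pred <- as.numeric(f$feats %*% params$wh + params$bh)
  list(pred = pred, feats = f$feats, cache = f$cache)
}

regnet_backward <- function(params, cache, feats, dpred) {
  d4 <- dim(cache$p4); P4 <- d4[1] * d4[2]
  dwh <- as.numeric(t(feats) %*% dpred)
  dbh <- sum(dpred)
  # d feats: N x C -> spread over spatial positions of p4
  dfeat <- outer(dpred, params$wh)           # N x C
  dp4 <- array(0, d4)
  for (n in seq_len(d4[4])) {
    dp4[, , , n] <- rep(dfeat[n, ] / P4, each = P4)
  }
  da4 <- nn_relu_bwd(cache$z4, nn_pool2_bwd(dp4, dim(cache$a4)))
  g4 <- nn_conv3_bwd(cache$p3, params$w4, da4)
  da3 <- nn_relu_bwd(cache$z3, nn_pool2_bwd(g4$dx, dim(cache$a3)))
  g3 <- nn_conv3_bwd(cache$p2, params$w3, da3)
  da2 <- nn_relu_bwd(cache$z2, nn_pool2_bwd(g3$dx, dim(cache$a2)))
  g2 <- nn_conv3_bwd(cache$p1, params$w2, da2)
  da1 <- nn_relu_bwd(cache$z1, nn_pool2_bwd(g2$dx, dim(cache$a1)))
  g1 <- nn_conv3_bwd(cache$x, params$w1, da1)
  list(w1 = g1$dW, b1 = g1$db, w2 = g2$dW, b2 = g2$db,
       w3 = g3$dW, b3 = g3$db, w4 = g4$dW, b4 = g4$db,
       wh = dwh, bh = dbh)
}
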