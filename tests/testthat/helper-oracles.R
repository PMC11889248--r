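# Independent brute-force oracles used across the suite. These deliberately
# use plain loops and textbook formulas, never the package's own fast paths.

rand_fmap <- function(C, H, W) array(rnorm(C * H * W), c(C, H, W))

# per-channel mean via an explicit double loop over (i, j)
oracle_channel_mean <- function(x) {
  d <- dim(x)
  z <- numeric(d[1L])
  for (c in seq_len(d[1L])) {
    acc <- 0
    for (i in seq_len(d[2L])) for (j in seq_len(d[3L])) acc <- acc + x[c, i, j]
    z[c] <- acc / (d[2L] * d[3L])
  }
  z
}

oracle_se_excite <- function(z, w1, w2) {
  h <- as.vector(w1 %*% z)
  h[h < 0] <- 0
  1 / (1 + exp(-as.vector(w2 %*% h)))
}

# naive dense 2-D convolution with zero padding (loops over every output
# element and kernel tap)
oracle_conv <- function(x, w, stride = 1L, pad = 1L) {
  C <- dim(x)[1L]; H <- dim(x)[2L]; W <- dim(x)[3L]
  Co <- dim(w)[1L]; k <- dim(w)[3L]
  Ho <- (H + 2L * pad - k) %/% stride + 1L
  Wo <- (W + 2L * pad - k) %/% stride + 1L
  xp <- array(0, c(C, H + 2L * pad, W + 2L * pad))
  xp[, pad + seq_len(H), pad + seq_len(W)] <- x
  y <- array(0, c(Co, Ho, Wo))
  for (co in seq_len(Co)) for (i in seq_len(Ho)) for (j in seq_len(Wo)) {
    acc <- 0
    for (ci in seq_len(C)) for (u in seq_len(k)) for (v in seq_len(k))
      acc <- acc + w[co, ci, u, v] * xp[ci, (i - 1L) * stride + u, (j - 1L) * stride + v]
    y[co, i, j] <- acc
  }
  y
}

# naive depthwise convolution: one k x k kernel per channel
oracle_depthwise <- function(x, w, stride = 1L, pad = 1L) {
  C <- dim(x)[1L]; k <- dim(w)[2L]
  w4 <- array(0, c(C, C, k, k))
  for (c in seq_len(C)) w4[c, c, , ] <- w[c, , ]
  oracle_conv(x, w4, stride, pad)
}

# staged NAM oracle: normalize, attention weights, elementwise gate,
# reconstruction, each as a separate array computation
oracle_nam <- function(x, params) {
  C <- dim(x)[1L]
  mu <- params$norm$mean
  va <- params$norm$var
  if (is.null(mu)) {
    mu <- numeric(C); va <- numeric(C)
    for (c in seq_len(C)) {
      mu[c] <- mean(x[c, , ])
      va[c] <- mean((x[c, , ] - mu[c])^2)
    }
  }
  eps <- if (is.null(params$norm$eps)) 1e-5 else params$norm$eps
  xhat <- x
  for (c in seq_len(C))
    xhat[c, , ] <- params$norm$gamma[c] * (x[c, , ] - mu[c]) / sqrt(va[c] + eps) +
      params$norm$beta[c]
  a <- x; y <- x; z <- x
  H <- dim(x)[2L]; W <- dim(x)[3L]
  for (i in seq_len(H)) for (j in seq_len(W)) {
    pre <- as.vector(params$att$weight %*% xhat[, i, j]) + params$att$bias
    a[, i, j] <- 1 / (1 + exp(-pre))
    y[, i, j] <- x[, i, j] * a[, i, j]
    z[, i, j] <- as.vector(params$recon$weight %*% y[, i, j]) + params$recon$bias
  }
  list(x_hat = xhat, a = a, y = y, z_out = z)
}

# pairwise-comparison ROC-AUC: wins + half-ties over all (pos, neg) pairs
oracle_auc_pairs <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# F1 from an explicitly tabulated contingency table
oracle_f1_confusion <- function(labels, predictions) {
  per <- numeric(2)
  for (k in c(0, 1)) {
    tp <- sum(labels == k & predictions == k)
    fp <- sum(labels != k & predictions == k)
    fn <- sum(labels == k & predictions != k)
    per[k + 1] <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }
  list(macro = mean(per), per_class = per)
}

# a small balanced in-memory dataset for pipeline/training tests
tiny_dataset <- function(n, positive_fraction = 0.5, seed = 1,
                         mode = "easy", side = 64) {
  generate_dataset(n, positive_fraction,
                   synthetic_image_spec(side = side, mode = mode), seed = seed)
}
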