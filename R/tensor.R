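# Core batched array primitives.
#
# Layout contract (used everywhere in the package): a feature map is
# channel-major, i.e. a 3-D array indexed (channel, row, column); batched
# tensors carry the batch as a trailing fourth dimension (C, H, W, N).
# All primitives below implement both the forward pass and the exact
# gradient so the network can be trained without an external framework.

sigmoid <- function(x) 1 / (1 + exp(-x))

silu <- function(x) x * sigmoid(x)

silu_grad <- function(x) {
  s <- sigmoid(x)
  s * (1 + x * (1 - s))
}

# add batch dimension to a single (C,H,W) map
.batch1 <- function(x) {
  d <- dim(x)
  array(x, c(d, 1L))
}

.unbatch1 <- function(x) {
  d <- dim(x)
  array(x, d[1:3])
}

.check_fmap <- function(x, what = "x") {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(sprintf("'%s' must be a 3-D (channel, row, column) array", what), call. = FALSE)
  if (any(dim(x) < 1L))
    stop(sprintf("'%s' has an empty dimension", what), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", what), call. = FALSE)
  invisible(x)
}

# zero-pad the two spatial dimensions of a (C,H,W,N) tensor
pad_hw <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, c(d[1L], d[2L] + 2L * pad, d[3L] + 2L * pad, d[4L]))
  out[, pad + seq_len(d[2L]), pad + seq_len(d[3L]), ] <- x
  out
}

unpad_hw <- function(x, pad, H, W) {
  if (pad == 0L) return(x)
  x[, pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
}

# Convolution forward. x: (Cin,H,W,N); w: (Cout, Cin/groups, k, k).
# groups must be 1 (dense) or Cin with Cout == Cin (depthwise).
# Implemented as k^2 stride-sampled shifted matrix products, which keeps
# everything inside BLAS.
conv2d_fwd <- function(x, w, b = NULL, stride = 1L, pad = 0L, groups = 1L) {
  d <- dim(x)
  cin <- d[1L]; H <- d[2L]; W <- d[3L]; N <- d[4L]
  cout <- dim(w)[1L]; k <- dim(w)[3L]
  depthwise <- groups > 1L
  if (depthwise && (groups != cin || cout != cin))
    stop("grouped convolution supported only for groups = 1 or depthwise (groups = in = out)", call. = FALSE)
  if (!depthwise && dim(w)[2L] != cin)
    stop(sprintf("weight expects %d input channels, got %d", dim(w)[2L], cin), call. = FALSE)
  xp <- pad_hw(x, pad)
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  L <- Ho * Wo * N
  ymat <- matrix(0, cout, L)
  for (u in seq_len(k)) {
    rows <- seq.int(u, by = stride, length.out = Ho)
    for (v in seq_len(k)) {
      cols <- seq.int(v, by = stride, length.out = Wo)
      xs <- xp[, rows, cols, , drop = FALSE]
      dim(xs) <- c(cin, L)
      if (depthwise) {
        ymat <- ymat + xs * w[, 1L, u, v]
      } else {
        ymat <- ymat + matrix(w[, , u, v], cout, cin) %*% xs
      }
    }
  }
  if (!is.null(b)) ymat <- ymat + b
  array(ymat, c(cout, Ho, Wo, N))
}

# Convolution backward: returns list(dx, dw, db).
conv2d_bwd <- function(x, w, dy, stride = 1L, pad = 0L, groups = 1L, need_db = FALSE) {
  d <- dim(x)
  cin <- d[1L]; H <- d[2L]; W <- d[3L]; N <- d[4L]
  cout <- dim(w)[1L]; k <- dim(w)[3L]
  depthwise <- groups > 1L
  dyd <- dim(dy)
  Ho <- dyd[2L]; Wo <- dyd[3L]
  L <- Ho * Wo * N
  dymat <- matrix(dy, cout, L)
  xp <- pad_hw(x, pad)
  dxp <- array(0, dim(xp))
  dw <- array(0, dim(w))
  for (u in seq_len(k)) {
    rows <- seq.int(u, by = stride, length.out = Ho)
    for (v in seq_len(k)) {
      cols <- seq.int(v, by = stride, length.out = Wo)
      xs <- xp[, rows, cols, , drop = FALSE]
      dim(xs) <- c(cin, L)
      if (depthwise) {
        dw[, 1L, u, v] <- rowSums(dymat * xs)
        dxs <- dymat * w[, 1L, u, v]
      } else {
        dw[, , u, v] <- dymat %*% t(xs)
        dxs <- crossprod(matrix(w[, , u, v], cout, cin), dymat)
      }
      dxp[, rows, cols, ] <- dxp[, rows, cols, , drop = FALSE] +
        array(dxs, c(cin, Ho, Wo, N))
    }
  }
  db <- if (need_db) rowSums(dymat) else NULL
  list(dx = unpad_hw(dxp, pad, H, W), dw = dw, db = db)
}

# Per-channel batch normalisation over (H, W, N).
bn_fwd <- function(x, gamma, beta, eps = 1e-5, mean = NULL, var = NULL) {
  d <- dim(x)
  C <- d[1L]
  xm <- matrix(x, C)
  training <- is.null(mean)
  if (training) {
    mean <- rowMeans(xm)
    var <- rowMeans(xm * xm) - mean * mean
    var <- pmax(var, 0)
  }
  if (!all(is.finite(mean)) || !all(is.finite(var)))
    stop("non-finite normalization statistics", call. = FALSE)
  invstd <- 1 / sqrt(var + eps)
  xhat <- (xm - mean) * invstd
  y <- gamma * xhat + beta
  list(y = array(y, d), xhat = xhat, invstd = invstd,
       mean = mean, var = var, m = prod(d[-1L]))
}

bn_bwd <- function(cache, gamma, dy, training = TRUE) {
  d <- dim(dy)
  C <- d[1L]
  dym <- matrix(dy, C)
  dxhat <- dym * gamma
  dgamma <- rowSums(dym * cache$xhat)
  dbeta <- rowSums(dym)
  if (training) {
    mdx <- rowMeans(dxhat)
    mdxx <- rowMeans(dxhat * cache$xhat)
    dx <- cache$invstd * (dxhat - mdx - cache$xhat * mdxx)
  } else {
    dx <- cache$invstd * dxhat
  }
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

# Layer normalisation on token matrices (d, B): normalise each column.
ln_fwd <- function(x, gamma, beta, eps = 1e-5) {
  dd <- nrow(x)
  mu <- colMeans(x)
  xc <- x - rep(mu, each = dd)
  v <- colMeans(xc * xc)
  invstd <- 1 / sqrt(v + eps)
  xhat <- xc * rep(invstd, each = dd)
  list(y = gamma * xhat + beta, xhat = xhat, invstd = invstd)
}

ln_bwd <- function(cache, gamma, dy) {
  dd <- nrow(dy)
  dxhat <- dy * gamma
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  mdx <- colMeans(dxhat)
  mdxx <- colMeans(dxhat * cache$xhat)
  dx <- (dxhat - rep(mdx, each = dd) - cache$xhat * rep(mdxx, each = dd)) *
    rep(cache$invstd, each = dd)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# Bilinear resampling of an (H, W, C) image to a square side x side image.
resize_bilinear <- function(pixels, side) {
  d <- dim(pixels)
  H <- d[1L]; W <- d[2L]
  if (H == side && W == side) return(pixels)
  # align centers: map output pixel center to input coordinates
  yy <- (seq_len(side) - 0.5) * H / side + 0.5
  xx <- (seq_len(side) - 0.5) * W / side + 0.5
  y0 <- pmin(pmax(floor(yy), 1L), H); y1 <- pmin(y0 + 1L, H)
  x0 <- pmin(pmax(floor(xx), 1L), W); x1 <- pmin(x0 + 1L, W)
  fy <- pmin(pmax(yy - y0, 0), 1); fx <- pmin(pmax(xx - x0, 0), 1)
  out <- array(0, c(side, side, d[3L]))
  wyA <- (1 - fy); wyB <- fy
  for (ch in seq_len(d[3L])) {
    pl <- pixels[, , ch]
    a <- pl[y0, x0, drop = FALSE] * wyA + pl[y1, x0, drop = FALSE] * wyB
    b <- pl[y0, x1, drop = FALSE] * wyA + pl[y1, x1, drop = FALSE] * wyB
    out[, , ch] <- a * rep(1 - fx, each = side) + b * rep(fx, each = side)
  }
  out
}

# Separable Gaussian blur on an (H, W, C) image; sd in pixels.
gaussian_blur <- function(pixels, sd) {
  if (sd <= 0) return(pixels)
  r <- max(1L, ceiling(3 * sd))
  g <- dnorm(seq(-r, r), sd = sd)
  g <- g / sum(g)
  d <- dim(pixels)
  # reflect-pad and convolve rows then columns, per channel
  blur1 <- function(m) {
    H <- nrow(m)
    idx <- c(rev(seq_len(r) + 1L), seq_len(H), H - seq_len(r))
    mp <- m[idx, , drop = FALSE]
    out <- matrix(0, H, ncol(m))
    for (t in seq_along(g)) out <- out + g[t] * mp[(t - 1L) + seq_len(H), , drop = FALSE]
    out
  }
  out <- pixels
  for (ch in seq_len(d[3L])) {
    m <- blur1(pixels[, , ch])
    out[, , ch] <- t(blur1(t(m)))
  }
  out
}
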