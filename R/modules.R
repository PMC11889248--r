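# Trainable module system.
#
# Each module is an environment with: kind, par (named list of trainable
# arrays), grad (accumulated gradients), buf (non-trainable buffers such as
# batch-norm running statistics), children (named list of sub-modules),
# hyper (static configuration) and cache (forward activations needed by the
# backward pass). mod_fwd()/mod_bwd() dispatch on kind. Parameters are
# addressed by slash-separated paths ("stage3/vit/transformer/enc1/attn.wqkv")
# for checkpointing and transfer matching.

new_module <- function(kind, par = list(), buf = list(), children = list(),
                       hyper = list()) {
  m <- new.env(parent = emptyenv())
  m$kind <- kind
  m$par <- par
  m$grad <- list()
  m$buf <- buf
  m$children <- children
  m$hyper <- hyper
  m$cache <- NULL
  m$frozen <- FALSE
  class(m) <- "mn_module"
  m
}

.acc_grad <- function(m, name, g) {
  if (is.null(m$grad[[name]])) m$grad[[name]] <- g
  else m$grad[[name]] <- m$grad[[name]] + g
  invisible(NULL)
}

# ---- audit hooks -----------------------------------------------------------

.mn_audit <- new.env(parent = emptyenv())
.mn_audit$active <- FALSE
.mn_audit$macs <- 0

.audit_add <- function(n) {
  if (isTRUE(.mn_audit$active)) .mn_audit$macs <- .mn_audit$macs + n
  invisible(NULL)
}

# ---- leaf constructors -----------------------------------------------------

mod_conv2d <- function(cin, cout, k, stride = 1L, pad = (k - 1L) %/% 2L,
                       groups = 1L, bias = FALSE) {
  fan_in <- k * k * cin / groups
  w <- array(rnorm(cout * (cin %/% groups) * k * k, sd = sqrt(2 / fan_in)),
             c(cout, cin %/% groups, k, k))
  par <- list(w = w)
  if (bias) par$b <- rep(0, cout)
  new_module("conv2d", par = par,
             hyper = list(stride = stride, pad = pad, groups = groups,
                          cin = cin, cout = cout, k = k))
}

mod_bn2d <- function(C, eps = 1e-5, momentum = 0.1) {
  new_module("bn2d",
             par = list(gamma = rep(1, C), beta = rep(0, C)),
             buf = list(rm = rep(0, C), rv = rep(1, C)),
             hyper = list(eps = eps, momentum = momentum))
}

mod_silu <- function() new_module("silu")

mod_linear <- function(din, dout, bias = TRUE, sd = sqrt(1 / din)) {
  par <- list(w = matrix(rnorm(dout * din, sd = sd), dout, din))
  if (bias) par$b <- rep(0, dout)
  new_module("linear", par = par, hyper = list(din = din, dout = dout))
}

mod_layernorm <- function(d, eps = 1e-5) {
  new_module("layernorm", par = list(gamma = rep(1, d), beta = rep(0, d)),
             hyper = list(eps = eps))
}

mod_mhsa <- function(d, heads) {
  stopifnot(d %% heads == 0L)
  new_module("mhsa",
             par = list(wqkv = matrix(rnorm(3 * d * d, sd = sqrt(1 / d)), 3L * d, d),
                        bqkv = rep(0, 3L * d),
                        wo = matrix(rnorm(d * d, sd = sqrt(1 / d)), d, d),
                        bo = rep(0, d)),
             hyper = list(d = d, heads = heads))
}

mod_se <- function(C, reduction = 4L) {
  hidden <- max(1L, C %/% reduction)
  new_module("se",
             par = list(w1 = matrix(rnorm(hidden * C, sd = sqrt(2 / C)), hidden, C),
                        w2 = matrix(rnorm(C * hidden, sd = sqrt(2 / hidden)), C, hidden)),
             hyper = list(C = C, reduction = reduction))
}

mod_nam <- function(C, eps = 1e-5, momentum = 0.1) {
  new_module("nam",
             par = list(gamma = rep(1, C), beta = rep(0, C),
                        wa = matrix(rnorm(C * C, sd = sqrt(2 / C)), C, C),
                        ba = rep(0, C),
                        wr = matrix(rnorm(C * C, sd = sqrt(2 / C)), C, C),
                        br = rep(0, C)),
             buf = list(rm = rep(0, C), rv = rep(1, C)),
             hyper = list(C = C, eps = eps, momentum = momentum))
}

mod_gap <- function() new_module("gap")

mod_seq <- function(...) {
  ch <- list(...)
  if (length(ch) == 1L && is.list(ch[[1L]]) && !inherits(ch[[1L]], "mn_module"))
    ch <- ch[[1L]]
  new_module("seq", children = ch)
}

# residual wrapper: y = x + body(x) when `use_res`, else body(x)
mod_residual <- function(body, use_res = TRUE) {
  new_module("residual", children = list(body = body),
             hyper = list(use_res = use_res))
}

conv_bn_act <- function(cin, cout, k, stride = 1L, groups = 1L, act = TRUE) {
  ch <- list(conv = mod_conv2d(cin, cout, k, stride, groups = groups),
             bn = mod_bn2d(cout))
  if (act) ch$act <- mod_silu()
  mod_seq(ch)
}

# Depth-Conv + PFCL replacement of a standard k x k convolution: a bias-free
# depthwise k x k followed by a pointwise 1 x 1, then the usual BN + SiLU.
dec_conv_bn_act <- function(cin, cout, k, stride = 1L, act = TRUE) {
  ch <- list(dw = mod_conv2d(cin, cin, k, stride, groups = cin),
             pw = mod_conv2d(cin, cout, 1L),
             bn = mod_bn2d(cout))
  if (act) ch$act <- mod_silu()
  mod_seq(ch)
}

.make_attention <- function(kind, C, reduction = 4L) {
  switch(kind,
         none = NULL,
         se = mod_se(C, reduction),
         nam = mod_nam(C),
         stop(sprintf("unknown attention kind '%s'", kind), call. = FALSE))
}

# MV2-DD inverted residual: 1x1 expand -> SEDD (depthwise 3x3 + channel
# attention) -> 1x1 linear projection, shortcut when stride 1 and the channel
# count is preserved.
mod_mv2 <- function(cin, cout, stride = 1L, expansion = 2L,
                    attention = "none", se_reduction = 4L) {
  h <- cin * expansion
  ch <- list(expand = conv_bn_act(cin, h, 1L),
             dw = mod_conv2d(h, h, 3L, stride, groups = h),
             dwbn = mod_bn2d(h),
             dwact = mod_silu())
  att <- .make_attention(attention, h, se_reduction)
  if (!is.null(att)) ch$att <- att
  ch$proj <- mod_conv2d(h, cout, 1L)
  ch$projbn <- mod_bn2d(cout)
  mod_residual(mod_seq(ch), use_res = stride == 1L && cin == cout)
}

transformer_encoder_layer <- function(d, heads, mlp_ratio = 2L) {
  hidden <- d * mlp_ratio
  mod_seq(list(
    attn_block = mod_residual(mod_seq(list(norm = mod_layernorm(d),
                                           attn = mod_mhsa(d, heads)))),
    ffn_block = mod_residual(mod_seq(list(norm = mod_layernorm(d),
                                          fc1 = mod_linear(d, hidden),
                                          act = mod_silu(),
                                          fc2 = mod_linear(hidden, d))))
  ))
}

# MobileViT block (-DD): local representation (optional channel attention,
# then a 3x3 conv — decomposed into Depth-Conv + PFCL when `decomposed` —
# and a 1x1 projection to the embedding dim), unfold into patches,
# transformer encoder layers attending across patches, fold, 1x1 back to C,
# concatenation with the input and a 3x3 fusion over 2C channels.
mod_mvit <- function(C, d, depth, heads = 4L, mlp_ratio = 2L,
                     patch = c(2L, 2L), decomposed = FALSE,
                     attention = "none", se_reduction = 4L,
                     attention_first = TRUE) {
  ch <- list()
  att <- .make_attention(attention, C, se_reduction)
  if (!is.null(att)) ch$att <- att
  ch$local <- if (decomposed) dec_conv_bn_act(C, C, 3L) else conv_bn_act(C, C, 3L)
  ch$proj <- conv_bn_act(C, d, 1L)
  enc <- lapply(seq_len(depth), function(i) transformer_encoder_layer(d, heads, mlp_ratio))
  names(enc) <- paste0("enc", seq_len(depth))
  ch$transformer <- mod_seq(enc)
  ch$back <- conv_bn_act(d, C, 1L)
  ch$fusion <- if (decomposed) dec_conv_bn_act(2L * C, C, 3L) else conv_bn_act(2L * C, C, 3L)
  new_module("mvit", children = ch,
             hyper = list(C = C, d = d, depth = depth, ph = patch[1L],
                          pw = patch[2L], attention_first = attention_first))
}

# ---- forward ---------------------------------------------------------------

mod_fwd <- function(m, x, training = FALSE) {
  switch(m$kind,
    conv2d = {
      m$cache <- list(x = x)
      y <- conv2d_fwd(x, m$par$w, m$par$b, m$hyper$stride, m$hyper$pad, m$hyper$groups)
      if (isTRUE(.mn_audit$active)) {
        dd <- dim(y)
        .audit_add(m$hyper$k^2 * (m$hyper$cin / m$hyper$groups) * m$hyper$cout *
                     dd[2L] * dd[3L] * dd[4L])
      }
      y
    },
    bn2d = {
      if (training) {
        cc <- bn_fwd(x, m$par$gamma, m$par$beta, m$hyper$eps)
        mom <- m$hyper$momentum
        unb <- if (cc$m > 1) cc$m / (cc$m - 1) else 1
        m$buf$rm <- (1 - mom) * m$buf$rm + mom * cc$mean
        m$buf$rv <- (1 - mom) * m$buf$rv + mom * cc$var * unb
      } else {
        cc <- bn_fwd(x, m$par$gamma, m$par$beta, m$hyper$eps,
                     mean = m$buf$rm, var = m$buf$rv)
      }
      cc$training <- training
      m$cache <- cc
      cc$y
    },
    silu = {
      m$cache <- list(x = x)
      silu(x)
    },
    linear = {
      dd <- dim(x)
      xm <- if (length(dd) > 2L) matrix(x, dd[1L]) else x
      m$cache <- list(x = xm, dims = dd)
      y <- m$par$w %*% xm
      if (!is.null(m$par$b)) y <- y + m$par$b
      .audit_add(m$hyper$din * m$hyper$dout * ncol(xm))
      if (length(dd) > 2L) {
        array(y, c(m$hyper$dout, dd[-1L]))
      } else y
    },
    layernorm = {
      dd <- dim(x)
      xm <- if (length(dd) > 2L) matrix(x, dd[1L]) else x
      cc <- ln_fwd(xm, m$par$gamma, m$par$beta, m$hyper$eps)
      cc$dims <- dd
      m$cache <- cc
      if (length(dd) > 2L) array(cc$y, dd) else cc$y
    },
    mhsa = .mhsa_fwd(m, x),
    se = .se_fwd(m, x),
    nam = .nam_fwd(m, x, training),
    gap = {
      dd <- dim(x)
      m$cache <- list(dims = dd)
      z <- colMeans(aperm(array(x, c(dd[1L], dd[2L] * dd[3L], dd[4L])), c(2L, 1L, 3L)))
      matrix(z, dd[1L], dd[4L])
    },
    seq = {
      for (ch in m$children) x <- mod_fwd(ch, x, training)
      x
    },
    residual = {
      y <- mod_fwd(m$children$body, x, training)
      if (isTRUE(m$hyper$use_res)) x + y else y
    },
    mvit = .mvit_fwd(m, x, training),
    stop("unknown module kind: ", m$kind)
  )
}

# ---- backward --------------------------------------------------------------

mod_bwd <- function(m, dy) {
  switch(m$kind,
    conv2d = {
      r <- conv2d_bwd(m$cache$x, m$par$w, dy, m$hyper$stride, m$hyper$pad,
                      m$hyper$groups, need_db = !is.null(m$par$b))
      .acc_grad(m, "w", r$dw)
      if (!is.null(r$db)) .acc_grad(m, "b", r$db)
      r$dx
    },
    bn2d = {
      r <- bn_bwd(m$cache, m$par$gamma, dy, training = isTRUE(m$cache$training))
      .acc_grad(m, "gamma", r$dgamma)
      .acc_grad(m, "beta", r$dbeta)
      r$dx
    },
    silu = dy * silu_grad(m$cache$x),
    linear = {
      dd <- m$cache$dims
      dym <- if (length(dd) > 2L) matrix(dy, m$hyper$dout) else dy
      .acc_grad(m, "w", dym %*% t(m$cache$x))
      if (!is.null(m$par$b)) .acc_grad(m, "b", rowSums(dym))
      dx <- crossprod(m$par$w, dym)
      if (length(dd) > 2L) array(dx, dd) else dx
    },
    layernorm = {
      dd <- m$cache$dims
      dym <- if (length(dd) > 2L) matrix(dy, dd[1L]) else dy
      r <- ln_bwd(m$cache, m$par$gamma, dym)
      .acc_grad(m, "gamma", r$dgamma)
      .acc_grad(m, "beta", r$dbeta)
      if (length(dd) > 2L) array(r$dx, dd) else r$dx
    },
    mhsa = .mhsa_bwd(m, dy),
    se = .se_bwd(m, dy),
    nam = .nam_bwd(m, dy),
    gap = {
      dd <- m$cache$dims
      hw <- dd[2L] * dd[3L]
      g <- dy / hw                      # (C, N)
      array(g[, rep(seq_len(dd[4L]), each = hw)], dd)
    },
    seq = {
      for (ch in rev(m$children)) dy <- mod_bwd(ch, dy)
      dy
    },
    residual = {
      dx <- mod_bwd(m$children$body, dy)
      if (isTRUE(m$hyper$use_res)) dx + dy else dx
    },
    mvit = .mvit_bwd(m, dy),
    stop("unknown module kind: ", m$kind)
  )
}

# ---- multi-head self-attention --------------------------------------------

.mhsa_fwd <- function(m, x) {
  d <- m$hyper$d; nh <- m$hyper$heads
  dd <- dim(x)                         # (d, L, B)
  L <- dd[2L]; B <- dd[3L]
  dh <- d %/% nh
  scale <- 1 / sqrt(dh)
  xm <- matrix(x, d)
  qkv <- m$par$wqkv %*% xm + m$par$bqkv
  .audit_add(3 * d * d * L * B)
  q <- array(qkv[seq_len(d), , drop = FALSE], c(dh, nh, L, B))
  k <- array(qkv[d + seq_len(d), , drop = FALSE], c(dh, nh, L, B))
  v <- array(qkv[2L * d + seq_len(d), , drop = FALSE], c(dh, nh, L, B))
  P <- array(0, c(L, L, nh, B))
  o <- array(0, c(dh, nh, L, B))
  for (b in seq_len(B)) {
    for (h in seq_len(nh)) {
      Q <- matrix(q[, h, , b], dh, L)
      K <- matrix(k[, h, , b], dh, L)
      V <- matrix(v[, h, , b], dh, L)
      S <- crossprod(Q, K) * scale
      S <- exp(S - apply(S, 1L, max))
      Pm <- S / rowSums(S)
      P[, , h, b] <- Pm
      o[, h, , b] <- V %*% t(Pm)
    }
  }
  .audit_add(2 * L * L * d * B)        # scores + attention-weighted values
  om <- matrix(o, d)
  y <- m$par$wo %*% om + m$par$bo
  .audit_add(d * d * L * B)
  m$cache <- list(xm = xm, q = q, k = k, v = v, P = P, om = om, dims = dd)
  array(y, dd)
}

.mhsa_bwd <- function(m, dy) {
  cc <- m$cache
  d <- m$hyper$d; nh <- m$hyper$heads
  dd <- cc$dims
  L <- dd[2L]; B <- dd[3L]
  dh <- d %/% nh
  scale <- 1 / sqrt(dh)
  dym <- matrix(dy, d)
  .acc_grad(m, "wo", dym %*% t(cc$om))
  .acc_grad(m, "bo", rowSums(dym))
  do <- array(crossprod(m$par$wo, dym), c(dh, nh, L, B))
  dq <- array(0, c(dh, nh, L, B)); dk <- dq; dv <- dq
  for (b in seq_len(B)) {
    for (h in seq_len(nh)) {
      G <- matrix(do[, h, , b], dh, L)
      Pm <- matrix(cc$P[, , h, b], L, L)
      Q <- matrix(cc$q[, h, , b], dh, L)
      K <- matrix(cc$k[, h, , b], dh, L)
      V <- matrix(cc$v[, h, , b], dh, L)
      dv[, h, , b] <- G %*% Pm
      dP <- crossprod(G, V)            # (L, L)
      rs <- rowSums(dP * Pm)
      dS <- Pm * (dP - rs) * scale
      dq[, h, , b] <- K %*% t(dS)
      dk[, h, , b] <- Q %*% dS
    }
  }
  dqkv <- rbind(matrix(dq, d), matrix(dk, d), matrix(dv, d))
  .acc_grad(m, "wqkv", dqkv %*% t(cc$xm))
  .acc_grad(m, "bqkv", rowSums(dqkv))
  array(crossprod(m$par$wqkv, dqkv), dd)
}

# ---- SE layer (batched) ----------------------------------------------------

.se_fwd <- function(m, x) {
  dd <- dim(x)
  C <- dd[1L]; hw <- dd[2L] * dd[3L]; N <- dd[4L]
  z <- colMeans(aperm(array(x, c(C, hw, N)), c(2L, 1L, 3L)))   # (C, N)
  z <- matrix(z, C, N)
  h <- pmax(m$par$w1 %*% z, 0)
  s <- sigmoid(m$par$w2 %*% h)
  sx <- s[, rep(seq_len(N), each = hw), drop = FALSE]
  m$cache <- list(x = x, z = z, h = h, s = s, dims = dd)
  array(matrix(x, C) * sx, dd)
}

.se_bwd <- function(m, dy) {
  cc <- m$cache
  dd <- cc$dims
  C <- dd[1L]; hw <- dd[2L] * dd[3L]; N <- dd[4L]
  dym <- matrix(dy, C)
  xm <- matrix(cc$x, C)
  sx <- cc$s[, rep(seq_len(N), each = hw), drop = FALSE]
  dx <- dym * sx
  prod_ <- dym * xm
  ds <- colSums(aperm(array(prod_, c(C, hw, N)), c(2L, 1L, 3L)))
  ds <- matrix(ds, C, N)
  dpre <- ds * cc$s * (1 - cc$s)
  .acc_grad(m, "w2", dpre %*% t(cc$h))
  dh <- crossprod(m$par$w2, dpre)
  dh[cc$h <= 0] <- 0
  .acc_grad(m, "w1", dh %*% t(cc$z))
  dz <- crossprod(m$par$w1, dh)                                # (C, N)
  dx <- dx + dz[, rep(seq_len(N), each = hw), drop = FALSE] / hw
  array(dx, dd)
}

# ---- NAM layer (batched) ---------------------------------------------------

.nam_fwd <- function(m, x, training) {
  dd <- dim(x)
  C <- dd[1L]
  if (training) {
    bn <- bn_fwd(x, m$par$gamma, m$par$beta, m$hyper$eps)
    mom <- m$hyper$momentum
    unb <- if (bn$m > 1) bn$m / (bn$m - 1) else 1
    m$buf$rm <- (1 - mom) * m$buf$rm + mom * bn$mean
    m$buf$rv <- (1 - mom) * m$buf$rv + mom * bn$var * unb
  } else {
    bn <- bn_fwd(x, m$par$gamma, m$par$beta, m$hyper$eps,
                 mean = m$buf$rm, var = m$buf$rv)
  }
  xhat <- matrix(bn$y, C)
  a <- sigmoid(m$par$wa %*% xhat + m$par$ba)
  xm <- matrix(x, C)
  y <- xm * a
  z <- m$par$wr %*% y + m$par$br
  .audit_add(2 * C * C * ncol(xm))
  m$cache <- list(bn = bn, bn_training = training, xhat = xhat, a = a,
                  xm = xm, y = y, dims = dd)
  array(z, dd)
}

.nam_bwd <- function(m, dy) {
  cc <- m$cache
  dd <- cc$dims
  C <- dd[1L]
  dzm <- matrix(dy, C)
  .acc_grad(m, "wr", dzm %*% t(cc$y))
  .acc_grad(m, "br", rowSums(dzm))
  dyw <- crossprod(m$par$wr, dzm)       # grad wrt y = x * a
  dx <- dyw * cc$a
  da <- dyw * cc$xm
  dpre <- da * cc$a * (1 - cc$a)
  .acc_grad(m, "wa", dpre %*% t(cc$xhat))
  .acc_grad(m, "ba", rowSums(dpre))
  dxhat <- crossprod(m$par$wa, dpre)
  r <- bn_bwd(cc$bn, m$par$gamma, array(dxhat, dd), training = isTRUE(cc$bn_training))
  .acc_grad(m, "gamma", r$dgamma)
  .acc_grad(m, "beta", r$dbeta)
  array(dx, dd) + r$dx
}

# ---- MobileViT block -------------------------------------------------------

.mvit_fwd <- function(m, x, training) {
  hp <- m$hyper
  ch <- m$children
  x0 <- x
  z <- x
  att_first <- !isFALSE(hp$attention_first)
  if (!is.null(ch$att) && att_first) z <- mod_fwd(ch$att, z, training)
  z <- mod_fwd(ch$local, z, training)
  if (!is.null(ch$att) && !att_first) z <- mod_fwd(ch$att, z, training)
  z <- mod_fwd(ch$proj, z, training)
  dz <- dim(z)                          # (d, H, W, N)
  if (dz[2L] %% hp$ph != 0L || dz[3L] %% hp$pw != 0L)
    stop(sprintf("patch size %dx%d does not divide feature map %dx%d",
                 hp$ph, hp$pw, dz[2L], dz[3L]), call. = FALSE)
  t4 <- unfold4(z, hp$ph, hp$pw)        # (d, P, Np, N)
  dt <- dim(t4)
  tok <- aperm(t4, c(1L, 3L, 2L, 4L))   # (d, Np, P, N): attend across patches
  dim(tok) <- c(dt[1L], dt[3L], dt[2L] * dt[4L])
  tok <- mod_fwd(ch$transformer, tok, training)
  dim(tok) <- c(dt[1L], dt[3L], dt[2L], dt[4L])
  t4 <- aperm(tok, c(1L, 3L, 2L, 4L))
  z <- fold4(t4, dz[2L], dz[3L], hp$ph, hp$pw)
  z <- mod_fwd(ch$back, z, training)
  cat_ <- array(0, c(2L * hp$C, dz[2L], dz[3L], dz[4L]))
  cat_[seq_len(hp$C), , , ] <- x0
  cat_[hp$C + seq_len(hp$C), , , ] <- z
  m$cache <- list(dz = dz, dt = dt)
  mod_fwd(ch$fusion, cat_, training)
}

.mvit_bwd <- function(m, dy) {
  hp <- m$hyper
  ch <- m$children
  cc <- m$cache
  dcat <- mod_bwd(ch$fusion, dy)
  dx0 <- dcat[seq_len(hp$C), , , , drop = FALSE]
  dz <- dcat[hp$C + seq_len(hp$C), , , , drop = FALSE]
  dz <- mod_bwd(ch$back, dz)
  t4 <- unfold4(dz, hp$ph, hp$pw)
  tok <- aperm(t4, c(1L, 3L, 2L, 4L))
  dim(tok) <- c(cc$dt[1L], cc$dt[3L], cc$dt[2L] * cc$dt[4L])
  tok <- mod_bwd(ch$transformer, tok)
  dim(tok) <- c(cc$dt[1L], cc$dt[3L], cc$dt[2L], cc$dt[4L])
  t4 <- aperm(tok, c(1L, 3L, 2L, 4L))
  dz <- fold4(t4, cc$dz[2L], cc$dz[3L], hp$ph, hp$pw)
  dz <- mod_bwd(ch$proj, dz)
  att_first <- !isFALSE(hp$attention_first)
  if (!is.null(ch$att) && !att_first) dz <- mod_bwd(ch$att, dz)
  dz <- mod_bwd(ch$local, dz)
  if (!is.null(ch$att) && att_first) dz <- mod_bwd(ch$att, dz)
  dx0 + dz
}

# ---- tree utilities --------------------------------------------------------

walk_modules <- function(m, fn, path = "") {
  fn(m, path)
  chn <- names(m$children)
  for (i in seq_along(m$children)) {
    nm <- if (is.null(chn) || chn[i] == "") as.character(i) else chn[i]
    walk_modules(m$children[[i]], fn,
                 if (nzchar(path)) paste0(path, "/", nm) else nm)
  }
  invisible(NULL)
}

collect_params <- function(m, buffers = FALSE) {
  out <- list()
  walk_modules(m, function(mod, path) {
    for (nm in names(mod$par))
      out[[paste0(path, ".", nm)]] <<- mod$par[[nm]]
    if (buffers)
      for (nm in names(mod$buf))
        out[[paste0(path, "#", nm)]] <<- mod$buf[[nm]]
  })
  out
}

assign_params <- function(m, flat) {
  walk_modules(m, function(mod, path) {
    for (nm in names(mod$par)) {
      key <- paste0(path, ".", nm)
      if (!is.null(flat[[key]])) {
        v <- flat[[key]]
        if (!is.null(dim(mod$par[[nm]]))) dim(v) <- dim(mod$par[[nm]])
        mod$par[[nm]] <- v
      }
    }
    for (nm in names(mod$buf)) {
      key <- paste0(path, "#", nm)
      if (!is.null(flat[[key]])) mod$buf[[nm]] <- flat[[key]]
    }
  })
  invisible(m)
}

zero_grads <- function(m) {
  walk_modules(m, function(mod, path) mod$grad <- list())
  invisible(m)
}

module_param_count <- function(m) {
  n <- 0L
  walk_modules(m, function(mod, path) {
    for (p in mod$par) n <<- n + length(p)
  })
  n
}

# per-leaf parameter breakdown, named by path
module_param_breakdown <- function(m) {
  paths <- character(); counts <- integer()
  walk_modules(m, function(mod, path) {
    np <- sum(vapply(mod$par, length, 1L))
    if (np > 0L) {
      paths <<- c(paths, if (nzchar(path)) path else mod$kind)
      counts <<- c(counts, np)
    }
  })
  data.frame(layer = paths, parameters = counts, stringsAsFactors = FALSE)
}
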