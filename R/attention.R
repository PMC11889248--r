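# Channel attention operators: squeeze-and-excitation (SE) and the
# normalization-based attention module (NAM). These are the functional,
# single-map forms used throughout the blocks; the trainable layer wrappers
# live in modules.R and call the same arithmetic.

#' Squeeze: global average pooling per channel
#'
#' Compresses each channel of a feature map into a single scalar,
#' `z[c] = mean over (i, j) of x[c, i, j]` — the squeeze stage of SE
#' attention.
#'
#' @param x A `(C, H, W)` feature map.
#' @return A numeric vector of length `C`.
#' @examples
#' se_squeeze(feature_map(matrix(1:4, 2)))  # 2.5
#' @export
se_squeeze <- function(x) {
  .check_fmap(x)
  rowMeans(matrix(x, dim(x)[1L]))
}

#' Build squeeze-and-excitation MLP parameters
#'
#' The excitation stage is a two-layer bottleneck MLP: `C -> C/r -> C` with a
#' rectifier in between and a logistic squashing at the end. Biases are
#' omitted so the operator is exactly `s = sigmoid(W2 relu(W1 z))`. The
#' reduction ratio `r` controls the bottleneck width; `r = 4` keeps the
#' parameter count low while leaving enough capacity to rank channels.
#'
#' @param channels Number of channels `C`.
#' @param reduction Bottleneck reduction ratio `r`; must divide `channels`.
#' @param init `"he"` for random Kaiming-style initialisation (uses the
#'   current RNG state) or `"zero"`.
#' @return A list with matrices `w1` (`C/r x C`) and `w2` (`C x C/r`).
#' @export
se_params <- function(channels, reduction = 4L, init = c("he", "zero")) {
  init <- match.arg(init)
  if (channels %% reduction != 0L)
    stop("'reduction' must divide 'channels'", call. = FALSE)
  hidden <- channels %/% reduction
  if (init == "zero") {
    list(w1 = matrix(0, hidden, channels), w2 = matrix(0, channels, hidden))
  } else {
    list(w1 = matrix(rnorm(hidden * channels, sd = sqrt(2 / channels)), hidden, channels),
         w2 = matrix(rnorm(channels * hidden, sd = sqrt(2 / hidden)), channels, hidden))
  }
}

#' Excitation: channel weights from squeezed statistics
#'
#' Computes `s = sigmoid(w2 %*% relu(w1 %*% z))`; every weight lies strictly
#' in (0, 1).
#'
#' @param z Numeric vector of per-channel statistics (length `C`).
#' @param params A list with `w1` (`C/r x C`) and `w2` (`C x C/r`), e.g. from
#'   [se_params()].
#' @return Numeric vector `s` of length `C`.
#' @export
se_excite <- function(z, params) {
  w1 <- params$w1; w2 <- params$w2
  if (ncol(w1) != length(z) || ncol(w2) != nrow(w1) || nrow(w2) != length(z))
    stop("excitation parameter shapes do not chain with length(z)", call. = FALSE)
  drop(sigmoid(w2 %*% pmax(w1 %*% z, 0)))
}

#' Squeeze-and-excitation channel reweighting
#'
#' Rescales every channel of `x` by its excitation weight:
#' `out[c, i, j] = x[c, i, j] * s[c]` with
#' `s = se_excite(se_squeeze(x), params)`. Channels carrying useful signal
#' are amplified, the rest damped, at the cost of a small bottleneck MLP.
#'
#' @inheritParams se_squeeze
#' @inheritParams se_excite
#' @return A `(C, H, W)` feature map of the same shape as `x`.
#' @export
se_block <- function(x, params) {
  s <- se_excite(se_squeeze(x), params)
  x * s  # recycles down the channel-major first dimension
}

#' Build NAM attention parameters
#'
#' The normalization-based attention module derives channel weights from a
#' normalized copy of the input: `x_hat = normalize(x)`,
#' `a = sigmoid(f_att(x_hat))`, `y = x * a`, `z = f_recon(y)`, where both
#' `f_att` and `f_recon` are 1x1 channel-preserving convolutions — the
#' cheapest operator consistent with the module's lightweight design.
#' Normalization is per-channel (batch-norm form); when no running
#' statistics are supplied the map's own spatial statistics are used.
#'
#' @param channels Number of channels `C`.
#' @param init `"he"` or `"zero"` (zero weights give attention 1/2
#'   everywhere).
#' @return A list with components `norm` (`gamma`, `beta`, optional `mean`,
#'   `var`, `eps`), `att` (`weight` `C x C`, `bias` length `C`) and `recon`
#'   (same shapes).
#' @export
nam_params <- function(channels, init = c("he", "zero")) {
  init <- match.arg(init)
  mk <- function() {
    if (init == "zero") matrix(0, channels, channels)
    else matrix(rnorm(channels * channels, sd = sqrt(2 / channels)), channels, channels)
  }
  list(norm = list(gamma = rep(1, channels), beta = rep(0, channels),
                   mean = NULL, var = NULL, eps = 1e-5),
       att = list(weight = mk(), bias = rep(0, channels)),
       recon = list(weight = mk(), bias = rep(0, channels)))
}

#' Normalization-based attention (NAM)
#'
#' Applies the normalize-weight-reconstruct pipeline to a feature map and
#' returns both the output and every intermediate stage (for inspection and
#' testing): the normalized input `x_hat`, the attention weights `a`
#' (strictly inside (0, 1)), the weighted features `y = x * a`, and the
#' reconstructed output `z_out = f_recon(y)`.
#'
#' @param x A `(C, H, W)` feature map.
#' @param params NAM parameters from [nam_params()]; `params$norm$mean` /
#'   `var` may carry externally estimated statistics, otherwise the map's own
#'   per-channel spatial statistics are used.
#' @param variant `"conv"` derives the attention logits with the `1 x 1`
#'   convolution `f_att` (the default pathway); `"bn_scale"` instead uses the
#'   normalisation scale factors as channel weights,
#'   `a = sigmoid(x_hat * gamma_c / sum(|gamma|))`, the weighting rule of the
#'   original normalization-based attention design.
#' @return A list with `z_out` (the output map) and `state` (fields `x_hat`,
#'   `a`, `y`, `z_out`).
#' @export
nam_attention <- function(x, params, variant = c("conv", "bn_scale")) {
  variant <- match.arg(variant)
  .check_fmap(x)
  C <- dim(x)[1L]
  nrm <- params$norm
  eps <- if (is.null(nrm$eps)) 1e-5 else nrm$eps
  xb <- .batch1(x)
  bn <- bn_fwd(xb, nrm$gamma, nrm$beta, eps = eps, mean = nrm$mean, var = nrm$var)
  x_hat <- .unbatch1(bn$y)
  xm <- matrix(x_hat, C)
  a <- if (variant == "conv") {
    sigmoid(params$att$weight %*% xm + params$att$bias)
  } else {
    sigmoid(xm * (nrm$gamma / sum(abs(nrm$gamma))))
  }
  y <- matrix(x, C) * a
  z <- params$recon$weight %*% y + params$recon$bias
  shape <- dim(x)
  state <- list(x_hat = x_hat,
                a = array(a, shape),
                y = array(y, shape),
                z_out = array(z, shape))
  list(z_out = state$z_out, state = state)
}
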