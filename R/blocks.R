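# Building blocks: convolution decomposition (Depth-Conv + PFCL), the SEDD
# unit, the MV2-DD inverted residual and the MobileViT block-DD.

#' Parameter count of a convolution layer
#'
#' Closed-form trainable-parameter count of a `k x k` convolution, either in
#' standard form (`k^2 * C_in * C_out / groups`, plus `C_out` biases when
#' `bias`) or decomposed into a bias-free depthwise `k x k` stage followed by
#' a pointwise `1 x 1` stage (`k^2 * C_in + C_in * C_out`). The decomposition
#' preserves the receptive field while shrinking the parameter count whenever
#' `C_in >= 2`.
#'
#' @param kernel Kernel size `k`.
#' @param in_channels,out_channels Channel counts.
#' @param groups Group count of the standard form (1 = dense, `in_channels` =
#'   depthwise).
#' @param bias Whether the standard form carries a bias vector.
#' @param decomposed Count the Depth-Conv + PFCL decomposition instead.
#' @return Integer parameter count.
#' @examples
#' conv_param_count(3, 2, 4)                     # 72
#' conv_param_count(3, 48, 48, decomposed = TRUE) # 2736
#' @export
conv_param_count <- function(kernel, in_channels, out_channels, groups = 1L,
                             bias = FALSE, decomposed = FALSE) {
  if (decomposed) {
    kernel^2 * in_channels + in_channels * out_channels
  } else {
    kernel^2 * in_channels * out_channels / groups + if (bias) out_channels else 0L
  }
}

#' Decomposed convolution: Depth-Conv followed by PFCL
#'
#' Replaces a standard `k x k`, `C_in -> C_out` convolution by two stages: a
#' channel-wise independent (depthwise) `k x k` convolution and a pixel-wise
#' fully-connected (pointwise `1 x 1`) cross-channel fusion. Both stages are
#' bias-free. Same-padding is applied so a stride-1 call preserves the
#' spatial dimensions.
#'
#' @param x A `(C, H, W)` feature map.
#' @param depthwise Depthwise kernels, array `(C, k, k)`.
#' @param pointwise Pointwise fusion matrix `(C_out, C)`.
#' @param stride Spatial stride of the depthwise stage.
#' @return A `(C_out, H', W')` feature map.
#' @export
decomposed_conv <- function(x, depthwise, pointwise, stride = 1L) {
  .check_fmap(x)
  C <- dim(x)[1L]
  if (dim(depthwise)[1L] != C)
    stop("depthwise kernel count does not match input channels", call. = FALSE)
  if (ncol(pointwise) != C)
    stop("pointwise matrix expects ", ncol(pointwise),
         " channels, input has ", C, call. = FALSE)
  k <- dim(depthwise)[2L]
  dw <- array(depthwise, c(C, 1L, k, k))
  h <- conv2d_fwd(.batch1(x), dw, stride = stride, pad = (k - 1L) %/% 2L, groups = C)
  pw <- array(pointwise, c(nrow(pointwise), C, 1L, 1L))
  .unbatch1(conv2d_fwd(h, pw))
}

#' SEDD unit: depthwise convolution with SE channel attention
#'
#' The SE-based deep separation-decentralization unit sitting inside every
#' MV2-DD block: a bias-free depthwise `3 x 3` convolution (which carries the
#' block's spatial stride) followed by squeeze-and-excitation reweighting of
#' the resulting channels.
#'
#' @param x A `(C, H, W)` feature map at the expanded width of the
#'   surrounding block.
#' @param weights A list with `depthwise` (array `(C, k, k)`) and `se` (a
#'   parameter list as in [se_params()]).
#' @param stride Spatial stride of the depthwise stage.
#' @return A `(C, H', W')` feature map.
#' @export
sedd <- function(x, weights, stride = 1L) {
  .check_fmap(x)
  C <- dim(x)[1L]
  k <- dim(weights$depthwise)[2L]
  dw <- array(weights$depthwise, c(C, 1L, k, k))
  h <- .unbatch1(conv2d_fwd(.batch1(x), dw, stride = stride,
                            pad = (k - 1L) %/% 2L, groups = C))
  se_block(h, weights$se)
}

#' Construct an MV2-DD inverted-residual block
#'
#' A MobileNetV2-style bottleneck: a `1 x 1` convolution expands the channels
#' by `expansion`, a depthwise `3 x 3` (wrapped with channel attention — the
#' SEDD unit when `attention = "se"`, its NAM twin when `"nam"`) filters
#' spatially, and a linear `1 x 1` projection maps back down. A shortcut is
#' added when the stride is 1 and the channel count is preserved. Weights are
#' initialised from the current RNG state.
#'
#' @param in_channels,out_channels Channel counts.
#' @param stride 1 or 2.
#' @param expansion Channel expansion factor of the bottleneck.
#' @param attention `"none"`, `"se"` or `"nam"`, applied on the expanded
#'   channels after the depthwise stage.
#' @param se_reduction SE bottleneck reduction ratio.
#' @return An `mn_module`; run it with [mv2_dd_block()].
#' @export
new_mv2_dd <- function(in_channels, out_channels, stride = 1L, expansion = 2L,
                       attention = c("se", "nam", "none"), se_reduction = 4L) {
  attention <- match.arg(attention)
  if (expansion < 1L) stop("invalid expansion factor", call. = FALSE)
  if (!stride %in% c(1L, 2L)) stop("stride must be 1 or 2", call. = FALSE)
  mod_mv2(in_channels, out_channels, stride, expansion, attention, se_reduction)
}

#' Run an MV2-DD block on a feature map
#'
#' @param x A `(C, H, W)` feature map.
#' @param block A block from [new_mv2_dd()].
#' @param training Use batch statistics (TRUE) or running statistics (FALSE)
#'   in the normalisation layers.
#' @return The output `(C_out, H', W')` feature map.
#' @export
mv2_dd_block <- function(x, block, training = TRUE) {
  .check_fmap(x)
  .unbatch1(mod_fwd(block, .batch1(x), training = training))
}

#' Construct a MobileViT block-DD
#'
#' The hybrid local/global block: a local representation (optional channel
#' attention on the input, a `3 x 3` convolution — decomposed into Depth-Conv
#' + PFCL when `decomposed` — and a `1 x 1` projection to the embedding
#' dimension), an unfold into `ph x pw` patches, `depth` transformer encoder
#' layers attending across patches, a fold back, a `1 x 1` return projection,
#' concatenation with the block input and a `3 x 3` fusion over the `2C`
#' concatenated channels (also decomposed when `decomposed`).
#'
#' @param channels Input/output channel count `C`.
#' @param embed_dim Transformer embedding dimension `d`.
#' @param depth Number of transformer encoder layers `L`.
#' @param heads Attention heads (must divide `embed_dim`).
#' @param mlp_ratio Feed-forward expansion ratio.
#' @param patch_size Integer pair `(ph, pw)`; must divide the feature-map
#'   dimensions at the point of use (no implicit padding).
#' @param decomposed Decompose the two `3 x 3` convolutions.
#' @param attention `"none"`, `"se"` or `"nam"` at the head of the local
#'   representation.
#' @param se_reduction SE bottleneck reduction ratio.
#' @param attention_first Place the channel attention on the block input,
#'   ahead of the `3 x 3` convolution (the default); `FALSE` applies it to
#'   the convolved local features instead, just before the `1 x 1`
#'   projection.
#' @return An `mn_module`; run it with [mobilevit_block_dd()].
#' @export
new_mobilevit_dd <- function(channels, embed_dim, depth, heads = 4L,
                             mlp_ratio = 2L, patch_size = c(2L, 2L),
                             decomposed = TRUE,
                             attention = c("nam", "se", "none"),
                             se_reduction = 4L, attention_first = TRUE) {
  attention <- match.arg(attention)
  mod_mvit(channels, embed_dim, depth, heads, mlp_ratio, patch_size,
           decomposed, attention, se_reduction, attention_first)
}

#' Run a MobileViT block-DD on a feature map
#'
#' @inheritParams mv2_dd_block
#' @param block A block from [new_mobilevit_dd()].
#' @return The output feature map; spatial size equals the input.
#' @export
mobilevit_block_dd <- function(x, block, training = TRUE) {
  .check_fmap(x)
  .unbatch1(mod_fwd(block, .batch1(x), training = training))
}

#' Count trainable parameters
#'
#' Total number of trainable scalars in a block or a full model (batch-norm
#' scale/shift and layer-norm scale/shift included; running statistics
#' excluded).
#'
#' @param object An `mn_module` or an `mnvit` model.
#' @return Integer count.
#' @export
count_parameters <- function(object) UseMethod("count_parameters")

#' @export
count_parameters.mn_module <- function(object) module_param_count(object)

#' @export
count_parameters.mnvit <- function(object) module_param_count(object$net)
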