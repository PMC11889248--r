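# Model assembly: the MobileViT-MN network, the ablation variant grid and
# the parameter / multiply-accumulate auditor.

# per-channel standardization constants applied to [0,1] images at load time
MN_PIXEL_MEAN <- 0.5
MN_PIXEL_SD <- 0.25

# macro structure shared by all variants (MobileViT-XXS scale):
# stem 3x3/2 -> 16, inverted-residual stages at widths 16/24/24/24/48/64/80
# with expansion 2, three transformer stages with embedding dims 64/80/96,
# 1x1 expansion to 320, global pooling, linear head.
MN_STRUCTURE <- list(
  stem_out = 16L,
  mv2 = list(
    stage1 = list(c(16L, 16L, 1L)),
    stage2 = list(c(16L, 24L, 2L), c(24L, 24L, 1L), c(24L, 24L, 1L)),
    stage3 = list(c(24L, 48L, 2L)),
    stage4 = list(c(48L, 64L, 2L)),
    stage5 = list(c(64L, 80L, 2L))
  ),
  vit_channels = c(48L, 64L, 80L),
  vit_dims = c(64L, 80L, 96L),
  head_width = 320L
)

#' Describe one model variant
#'
#' A declarative description of one row of the ablation grid: whether the two
#' `3 x 3` convolutions of each MobileViT block are decomposed into
#' Depth-Conv + PFCL, which channel attention sits inside the MV2 blocks and
#' which inside the MobileViT local representations, and the transformer
#' depth of each of the three MobileViT stages.
#'
#' @param name Label carried through audits and checkpoints.
#' @param decomposed Decompose the MobileViT-block convolutions.
#' @param mv2_attention,mb_attention `"none"`, `"se"` or `"nam"`.
#' @param transformer_depths Integer triple, one per MobileViT stage.
#' @param num_classes Classifier width (1000 for ImageNet-parity parameter
#'   audits, 2 for the micronucleus task).
#' @param input_size Square input side in pixels. The trunk downsamples by
#'   32, and the patches must tile every transformer-stage feature map
#'   exactly (no implicit padding), so `input_size / 32` must be a multiple
#'   of each patch dimension: multiples of 64 for the default 2x2 patches,
#'   multiples of 32 for 1x1 patches. The canonical full-resolution input
#'   is 256 px.
#' @param expansion MV2 bottleneck expansion factor.
#' @param se_reduction SE bottleneck reduction ratio.
#' @param heads Transformer heads.
#' @param mlp_ratio Transformer feed-forward expansion ratio.
#' @param patch_size Patch dimensions for the unfold step.
#' @return A `mn_variant_config` list.
#' @export
variant_config <- function(name = "custom", decomposed = FALSE,
                           mv2_attention = "none", mb_attention = "none",
                           transformer_depths = c(2L, 4L, 3L),
                           num_classes = 1000L, input_size = 256L,
                           expansion = 2L, se_reduction = 4L, heads = 4L,
                           mlp_ratio = 2L, patch_size = c(2L, 2L)) {
  stopifnot(length(transformer_depths) == 3L, all(transformer_depths >= 1L),
            num_classes >= 2L, input_size >= 32L)
  if (input_size %% 32L != 0L ||
      any((input_size %/% 32L) %% patch_size != 0L))
    stop(sprintf(paste0("input_size must be a multiple of 32 and the patches ",
                        "must tile the last feature map: with %dx%d patches ",
                        "use a multiple of %d"),
                 patch_size[1L], patch_size[2L],
                 32L * max(patch_size)), call. = FALSE)
  ok <- c("none", "se", "nam")
  if (!mv2_attention %in% ok || !mb_attention %in% ok)
    stop("attention must be one of 'none', 'se', 'nam'", call. = FALSE)
  structure(list(name = name, decomposed = decomposed,
                 mv2_attention = mv2_attention, mb_attention = mb_attention,
                 transformer_depths = as.integer(transformer_depths),
                 num_classes = as.integer(num_classes),
                 input_size = as.integer(input_size),
                 expansion = as.integer(expansion),
                 se_reduction = as.integer(se_reduction),
                 heads = as.integer(heads), mlp_ratio = as.integer(mlp_ratio),
                 patch_size = as.integer(patch_size)),
            class = "mn_variant_config")
}

#' Named presets for the ablation grid
#'
#' One preset per ablation row: the plain `MobileViT` baseline, `Model_DSC`
#' (both MobileViT-block convolutions decomposed), single-site attention
#' variants (`MV2_SE`, `MV2_NAM`, `Mb_SE`, `Mb_NAM`), transformer-depth
#' variants (`*_Mb_tr1`, `*_Mb_tr3` with all three stages at depth 1 or 3)
#' and the dual-attention models `MV2_SE_Mb_NAM` (the MobileViT-MN
#' configuration) and `MV2_NAM_Mb_SE`. All attention-bearing presets build on
#' the decomposed trunk.
#'
#' @param names Optional character vector selecting a subset.
#' @param ... Overrides forwarded to every [variant_config()] call
#'   (e.g. `num_classes = 2`, `input_size = 64`).
#' @return A named list of `mn_variant_config` objects.
#' @export
mn_presets <- function(names = NULL, ...) {
  mk <- function(nm, dec, mv2, mb, depths = c(2L, 4L, 3L))
    variant_config(name = nm, decomposed = dec, mv2_attention = mv2,
                   mb_attention = mb, transformer_depths = depths, ...)
  p <- list(
    MobileViT      = mk("MobileViT", FALSE, "none", "none"),
    Model_DSC      = mk("Model_DSC", TRUE, "none", "none"),
    MV2_SE         = mk("MV2_SE", TRUE, "se", "none"),
    MV2_SE_Mb_tr1  = mk("MV2_SE_Mb_tr1", TRUE, "se", "none", c(1L, 1L, 1L)),
    MV2_SE_Mb_tr3  = mk("MV2_SE_Mb_tr3", TRUE, "se", "none", c(3L, 3L, 3L)),
    MV2_NAM        = mk("MV2_NAM", TRUE, "nam", "none"),
    MV2_NAM_Mb_tr1 = mk("MV2_NAM_Mb_tr1", TRUE, "nam", "none", c(1L, 1L, 1L)),
    MV2_NAM_Mb_tr3 = mk("MV2_NAM_Mb_tr3", TRUE, "nam", "none", c(3L, 3L, 3L)),
    Mb_SE          = mk("Mb_SE", TRUE, "none", "se"),
    Mb_NAM         = mk("Mb_NAM", TRUE, "none", "nam"),
    MV2_SE_Mb_NAM  = mk("MV2_SE_Mb_NAM", TRUE, "se", "nam"),
    MV2_NAM_Mb_SE  = mk("MV2_NAM_Mb_SE", TRUE, "nam", "se")
  )
  if (!is.null(names)) {
    missing <- setdiff(names, base::names(p))
    if (length(missing))
      stop("unknown preset(s): ", paste(missing, collapse = ", "), call. = FALSE)
    p <- p[names]
  }
  p
}

#' Build a MobileViT-MN network
#'
#' Assembles the full network for one variant configuration: stem `3 x 3`
#' stride-2 convolution to 16 channels, five inverted-residual stages, three
#' MobileViT stages with the configured attention and transformer depths, a
#' `1 x 1` expansion to 320 channels, global average pooling and a linear
#' classification head.
#'
#' @param config A `mn_variant_config`, or a preset name (see
#'   [mn_presets()]).
#' @param seed Optional seed for weight initialisation.
#' @param ... When `config` is a preset name, overrides forwarded to
#'   [mn_presets()] (e.g. `num_classes = 2`).
#' @return An object of class `mnvit`: a list with `net` (the module tree)
#'   and `config`.
#' @examples
#' m <- build_model("Model_DSC", seed = 1)
#' count_parameters(m)   # 970008
#' @export
build_model <- function(config, seed = NULL, ...) {
  if (is.character(config)) config <- mn_presets(config, ...)[[1L]]
  if (!inherits(config, "mn_variant_config"))
    stop("'config' must be an mn_variant_config or a preset name", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  st <- MN_STRUCTURE
  mv2s <- function(stage) {
    blocks <- lapply(st$mv2[[stage]], function(b)
      mod_mv2(b[1L], b[2L], b[3L], config$expansion, config$mv2_attention,
              config$se_reduction))
    names(blocks) <- paste0("mv2_", seq_along(blocks))
    blocks
  }
  vit <- function(i) {
    mod_mvit(st$vit_channels[i], st$vit_dims[i], config$transformer_depths[i],
             config$heads, config$mlp_ratio, config$patch_size,
             config$decomposed, config$mb_attention, config$se_reduction)
  }
  net <- mod_seq(list(
    stem = conv_bn_act(3L, st$stem_out, 3L, stride = 2L),
    stage1 = mod_seq(mv2s("stage1")),
    stage2 = mod_seq(mv2s("stage2")),
    stage3 = mod_seq(c(mv2s("stage3"), list(vit = vit(1L)))),
    stage4 = mod_seq(c(mv2s("stage4"), list(vit = vit(2L)))),
    stage5 = mod_seq(c(mv2s("stage5"), list(vit = vit(3L)))),
    head = mod_seq(list(
      expand = conv_bn_act(80L, st$head_width, 1L),
      pool = mod_gap(),
      classifier = mod_linear(st$head_width, config$num_classes, bias = TRUE,
                              sd = 0.01)
    ))
  ))
  structure(list(net = net, config = config), class = "mnvit")
}

#' Forward pass of a model
#'
#' @param model An `mnvit` model.
#' @param x Batched input tensor `(3, H, W, N)`.
#' @param training Batch-statistics (training) or running-statistics
#'   (inference) mode for the normalisation layers.
#' @return Logit matrix `(num_classes, N)`.
#' @export
model_forward <- function(model, x, training = FALSE) {
  mod_fwd(model$net, x, training = training)
}

#' Count multiply-accumulate operations
#'
#' Runs one forward pass at the given input size and sums, over every
#' convolution and linear layer, `k^2 * (C_in / groups) * C_out * H_out *
#' W_out` multiply-accumulates, plus the attention matrix products
#' (query/key scores and attention-weighted values) and the NAM `1 x 1`
#' pathways. Batch-norm, activations and pooling are not counted.
#'
#' @param model An `mnvit` model.
#' @param input_size Square input side; defaults to the model's configured
#'   size.
#' @return Numeric MAC count for a single image.
#' @export
count_macs <- function(model, input_size = NULL) {
  if (is.null(input_size)) input_size <- model$config$input_size
  patch <- model$config$patch_size
  if (input_size %% 32L != 0L ||
      any((input_size %/% 32L) %% patch != 0L))
    stop("input_size must be a multiple of 32 that the patches tile exactly",
         call. = FALSE)
  x <- array(0, c(3L, input_size, input_size, 1L))
  .mn_audit$active <- TRUE
  .mn_audit$macs <- 0
  on.exit(.mn_audit$active <- FALSE)
  mod_fwd(model$net, x, training = FALSE)
  .mn_audit$macs
}

#' Audit the ablation variant grid
#'
#' Builds every requested preset and reports trainable parameters and
#' multiply-accumulates at the declared input size, one row per preset, with
#' the per-layer breakdown available through [summary.mnvit()]. The
#' baseline-versus-DSC parameter difference is attached as attribute
#' `baseline_dsc_diff` when both presets are present.
#'
#' @param presets Character vector of preset names (default: the full grid).
#' @param num_classes Head width used for the audit (1000 = ImageNet parity).
#' @param input_size Input side for the MAC count.
#' @param file Optional path; when given the table is also written as CSV.
#' @return A data.frame with columns `preset`, `parameters`, `macs`,
#'   `input_size`, `head_classes`.
#' @export
audit_variant_grid <- function(presets = names(mn_presets()),
                               num_classes = 1000L, input_size = 256L,
                               file = NULL) {
  cfgs <- mn_presets(presets, num_classes = num_classes,
                     input_size = input_size)
  rows <- lapply(cfgs, function(cfg) {
    model <- build_model(cfg, seed = 0L)
    data.frame(preset = cfg$name,
               parameters = count_parameters(model),
               macs = count_macs(model, input_size),
               input_size = input_size,
               head_classes = num_classes,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (all(c("MobileViT", "Model_DSC") %in% out$preset)) {
    attr(out, "baseline_dsc_diff") <-
      out$parameters[out$preset == "MobileViT"] -
      out$parameters[out$preset == "Model_DSC"]
  }
  if (!is.null(file)) utils::write.csv(out, file, row.names = FALSE)
  out
}

#' @export
print.mnvit <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("MobileViT-MN variant '%s'\n", cfg$name))
  cat(sprintf("  decomposed convs: %s | MV2 attention: %s | Mb attention: %s\n",
              cfg$decomposed, cfg$mv2_attention, cfg$mb_attention))
  cat(sprintf("  transformer depths: (%s) | classes: %d | input: %dx%d\n",
              paste(cfg$transformer_depths, collapse = ", "),
              cfg$num_classes, cfg$input_size, cfg$input_size))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @export
summary.mnvit <- function(object, ...) {
  bd <- module_param_breakdown(object$net)
  structure(list(config = object$config, breakdown = bd,
                 total = sum(bd$parameters)), class = "summary.mnvit")
}

#' @export
print.summary.mnvit <- function(x, ...) {
  cat(sprintf("Variant '%s': %s trainable parameters in %d weighted layers\n",
              x$config$name, format(x$total, big.mark = ","), nrow(x$breakdown)))
  top <- x$breakdown[order(-x$breakdown$parameters), ][seq_len(min(10L, nrow(x$breakdown))), ]
  cat("largest layers:\n")
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-55s %9d\n", top$layer[i], top$parameters[i]))
  invisible(x)
}

# standardize a list of (H, W, 3) images in [0,1] into a (3, s, s, N) batch
images_to_batch <- function(images, side) {
  N <- length(images)
  x <- array(0, c(3L, side, side, N))
  for (i in seq_len(N)) {
    img <- images[[i]]
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    if (dim(img)[3L] > 3L) img <- img[, , 1:3, drop = FALSE]
    img <- resize_bilinear(img, side)
    x[, , , i] <- aperm((img - MN_PIXEL_MEAN) / MN_PIXEL_SD, c(3L, 1L, 2L))
  }
  x
}

#' Predict from a model
#'
#' Resizes images to the model's input side with bilinear interpolation,
#' standardizes them with the package's fixed per-channel constants, and runs
#' a forward pass in inference mode.
#'
#' @param object An `mnvit` model.
#' @param images A list of `(H, W, 3)` arrays in `[0, 1]` (grayscale matrices
#'   are replicated to three channels), or a single such array.
#' @param type `"prob"` (softmax matrix, classes in rows), `"class"`
#'   (0-based class index; for the task head 0 = normal, 1 = micronucleus) or
#'   `"logits"`.
#' @param batch_size Images per forward pass.
#' @param ... Unused.
#' @return A matrix (`prob`/`logits`) or an integer vector (`class`).
#' @export
predict.mnvit <- function(object, images, type = c("prob", "class", "logits"),
                          batch_size = 32L, ...) {
  type <- match.arg(type)
  if (is.array(images) && length(dim(images)) == 3L) images <- list(images)
  side <- object$config$input_size
  N <- length(images)
  K <- object$config$num_classes
  logits <- matrix(0, K, N)
  for (start in seq(1L, N, by = batch_size)) {
    idx <- start:min(start + batch_size - 1L, N)
    xb <- images_to_batch(images[idx], side)
    logits[, idx] <- model_forward(object, xb, training = FALSE)
  }
  switch(type,
         logits = logits,
         prob = {
           e <- exp(logits - rep(apply(logits, 2L, max), each = K))
           e / rep(colSums(e), each = K)
         },
         class = max.col(t(logits), ties.method = "first") - 1L)
}
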