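# Dataset pipeline: stratified splitting, label-preserving augmentation and
# class rebalancing. The test split is never touched by augmentation.

#' Describe the augmentation policy
#'
#' Random rotation, horizontal/vertical flips and isotropic scaling. Rotation
#' and scaling resample bilinearly about the image centre with reflection
#' padding, so output dimensions always equal input dimensions; flips are
#' exact index reversals.
#'
#' @param rotation Maximum absolute rotation in degrees.
#' @param flip_h,flip_v Flip probabilities in `[0, 1]`.
#' @param scale Zoom factor range `(min, max)`; values above 1 zoom in.
#' @return An `augmentation_policy` list.
#' @export
augmentation_policy <- function(rotation = 30, flip_h = 0.5, flip_v = 0.5,
                                scale = c(0.8, 1.2)) {
  if (scale[1L] > scale[2L]) stop("scale min must not exceed max", call. = FALSE)
  if (any(c(flip_h, flip_v) < 0) || any(c(flip_h, flip_v) > 1))
    stop("flip probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(rotation = rotation, flip_h = flip_h, flip_v = flip_v,
                 scale = scale), class = "augmentation_policy")
}

# reflect an out-of-range coordinate back into [1, n] (mirror, no edge repeat)
.reflect_idx <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * (n - 1L)
  m <- (idx - 1L) %% period
  m <- pmin(m, period - m)
  m + 1L
}

# rotate (degrees, counter-clockwise) and zoom about the centre with
# bilinear resampling and reflection padding
affine_resample <- function(pixels, angle = 0, zoom = 1) {
  d <- dim(pixels)
  H <- d[1L]; W <- d[2L]
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  al <- angle * pi / 180
  ys <- matrix(rep(seq_len(H), times = W), H) - cy
  xs <- matrix(rep(seq_len(W), each = H), H) - cx
  # inverse map: rotate by -angle, then un-zoom
  sx <- (cos(al) * xs + sin(al) * ys) / zoom + cx
  sy <- (-sin(al) * xs + cos(al) * ys) / zoom + cy
  x0 <- floor(sx); y0 <- floor(sy)
  fx <- sx - x0; fy <- sy - y0
  x0r <- .reflect_idx(x0, W); x1r <- .reflect_idx(x0 + 1, W)
  y0r <- .reflect_idx(y0, H); y1r <- .reflect_idx(y0 + 1, H)
  out <- array(0, d)
  i00 <- cbind(as.vector(y0r), as.vector(x0r))
  i01 <- cbind(as.vector(y0r), as.vector(x1r))
  i10 <- cbind(as.vector(y1r), as.vector(x0r))
  i11 <- cbind(as.vector(y1r), as.vector(x1r))
  w00 <- as.vector((1 - fy) * (1 - fx)); w01 <- as.vector((1 - fy) * fx)
  w10 <- as.vector(fy * (1 - fx)); w11 <- as.vector(fy * fx)
  for (ch in seq_len(d[3L])) {
    pl <- pixels[, , ch]
    out[, , ch] <- matrix(pl[i00] * w00 + pl[i01] * w01 +
                            pl[i10] * w10 + pl[i11] * w11, H, W)
  }
  out
}

#' Apply the augmentation policy to one sample
#'
#' Draws a rotation angle, flip decisions and a zoom factor from a seeded
#' RNG and applies them. The label is preserved, the output dimensions equal
#' the input dimensions, and the sample is marked `origin = "augmented"`. An
#' identity policy (0 degrees, zero flip probability, unit scale) returns
#' the pixels bit-for-bit unchanged.
#'
#' @param sample An `image_sample` or a bare `(H, W, 3)` pixel array.
#' @param policy An [augmentation_policy()].
#' @param seed Integer seed for the draw.
#' @return The augmented sample (same type as the input).
#' @export
augment_image <- function(sample, policy, seed = 1L) {
  px <- if (inherits(sample, "image_sample")) sample$pixels else sample
  out <- with_seed(seed, {
    angle <- if (policy$rotation > 0) runif(1L, -policy$rotation, policy$rotation) else 0
    zoom <- if (policy$scale[1L] == policy$scale[2L]) policy$scale[1L]
            else runif(1L, policy$scale[1L], policy$scale[2L])
    do_h <- runif(1L) < policy$flip_h
    do_v <- runif(1L) < policy$flip_v
    y <- if (angle != 0 || zoom != 1) affine_resample(px, angle, zoom) else px
    if (do_h) y <- y[, rev(seq_len(dim(y)[2L])), , drop = FALSE]
    if (do_v) y <- y[rev(seq_len(dim(y)[1L])), , , drop = FALSE]
    y
  })
  if (inherits(sample, "image_sample")) {
    sample$pixels <- out
    sample$origin <- "augmented"
    sample
  } else out
}

#' Stratified train/validation/test split
#'
#' Assigns every manifest row to a split so that each class is divided in
#' the given proportions (within one sample per class and split, via
#' cumulative rounding) and the overall counts hit the exact totals.
#' Deterministic for a fixed seed.
#'
#' @param manifest A manifest data.frame (columns path, label, ...).
#' @param ratios Length-3 positive weights for train/val/test; normalised to
#'   sum to 1.
#' @param seed Integer seed for the per-class shuffles.
#' @return The manifest with its `split` column filled.
#' @export
split_dataset <- function(manifest, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  ratios <- ratios / sum(ratios)
  labs <- unique(manifest$label)
  if (length(labs) < 2L)
    stop("both classes must be present before splitting", call. = FALSE)
  splits <- c("train", "val", "test")
  manifest$split <- NA_character_
  with_seed(seed, {
    for (k in labs) {
      idx <- which(manifest$label == k)
      if (length(idx) < 3L)
        stop(sprintf("class %s has fewer samples than splits", k), call. = FALSE)
      idx <- sample(idx)
      counts <- diff(c(0L, round(cumsum(ratios) * length(idx))))
      manifest$split[idx] <- rep(splits, counts)
    }
  })
  manifest
}

#' Rebalance the training split
#'
#' Emulates the imbalance strategy of the study design: the minority class
#' of the *training* split is expanded with augmented copies while the
#' majority class is randomly downsampled (to `majority_cap` when given),
#' until the minority:majority ratio reaches `target_ratio` (default 1:1).
#' Validation and test rows pass through untouched; no augmented row can
#' ever land in the test split.
#'
#' @param manifest A manifest with the `split` column filled.
#' @param policy An [augmentation_policy()] used for the minority copies.
#' @param target_ratio Desired minority/majority count ratio.
#' @param seed Integer seed (subsampling and per-copy augmentation draws).
#' @param majority_cap Optional cap on the retained majority count.
#' @param images Named list of samples/pixel arrays keyed by manifest path;
#'   required for `mem:` manifests, optional for on-disk PNG manifests
#'   (which are read and written as files).
#' @return The rebalanced manifest; when `images` was supplied the full
#'   updated image list (including augmented copies) is attached as
#'   `attr(, "images")`.
#' @export
rebalance_train <- function(manifest, policy, target_ratio = 1, seed = 1L,
                            majority_cap = NULL, images = NULL) {
  tr <- manifest[manifest$split == "train", , drop = FALSE]
  rest <- manifest[manifest$split != "train", , drop = FALSE]
  cnt <- table(factor(tr$label, levels = c(0, 1)))
  minority <- if (cnt[["1"]] <= cnt[["0"]]) 1L else 0L
  majority <- 1L - minority
  n_min <- cnt[[as.character(minority)]]
  n_maj <- cnt[[as.character(majority)]]
  keep_maj <- if (is.null(majority_cap)) n_maj else min(n_maj, majority_cap)
  target_min <- round(keep_maj * target_ratio)
  if (target_min < n_min) {
    stop(sprintf(paste0("target ratio %.3g is unreachable without discarding raw ",
                        "minority samples; achievable ratio with the given cap is %.3g"),
                 target_ratio, n_min / keep_maj), call. = FALSE)
  }
  n_aug <- target_min - n_min
  min_rows <- tr[tr$label == minority, , drop = FALSE]
  maj_rows <- tr[tr$label == majority, , drop = FALSE]
  out <- with_seed(seed, {
    maj_keep <- maj_rows[sample(nrow(maj_rows), keep_maj), , drop = FALSE]
    aug_seeds <- sample.int(.Machine$integer.max - 1L, max(n_aug, 1L))
    list(maj_keep = maj_keep, aug_seeds = aug_seeds)
  })
  aug_rows <- NULL
  aug_images <- list()
  if (n_aug > 0L) {
    src_idx <- rep(seq_len(nrow(min_rows)), length.out = n_aug)
    aug_rows <- min_rows[src_idx, , drop = FALSE]
    src_paths <- aug_rows$path
    aug_rows$path <- sprintf("%s_aug%04d.png",
                             sub("\\.png$", "", src_paths), seq_len(n_aug))
    aug_rows$origin <- "augmented"
    aug_rows$seed <- out$aug_seeds[seq_len(n_aug)]
    for (i in seq_len(n_aug)) {
      src <- if (!is.null(images)) images[[src_paths[i]]]
             else png::readPNG(src_paths[i])
      if (inherits(src, "image_sample")) src <- src$pixels
      if (length(dim(src)) == 2L) src <- array(rep(src, 3L), c(dim(src), 3L))
      aug <- augment_image(src, policy, seed = aug_rows$seed[i])
      if (!is.null(images)) aug_images[[aug_rows$path[i]]] <- aug
      else png::writePNG(aug, aug_rows$path[i])
    }
  }
  res <- rbind(out$maj_keep, min_rows, aug_rows, rest)
  rownames(res) <- NULL
  if (!is.null(images)) attr(res, "images") <- c(images, aug_images)
  res
}

#' Write / read a dataset manifest
#'
#' Manifests are plain CSV files with columns `path,label,split,origin,seed`.
#'
#' @param manifest A manifest data.frame.
#' @param path File path.
#' @return `read_manifest` returns the manifest data.frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest[, c("path", "label", "split", "origin", "seed")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# resolve manifest rows to a list of (H, W, 3) pixel arrays
resolve_images <- function(manifest, images = NULL) {
  lapply(manifest$path, function(p) {
    img <- if (!is.null(images) && !is.null(images[[p]])) images[[p]]
           else if (grepl("\\.tiff?$", p, ignore.case = TRUE)) tiff::readTIFF(p)
           else png::readPNG(p)
    if (inherits(img, "image_sample")) img <- img$pixels
    if (length(dim(img)) == 2L) img <- array(rep(img, 3L), c(dim(img), 3L))
    img
  })
}

#' Expand a split with exact rotation/flip views
#'
#' Deterministic, interpolation-free augmentation: every image of the chosen
#' split gains copies rotated by multiples of 90 degrees and/or mirrored.
#' Because these views are exact index permutations they never fabricate
#' structures the way resampling near borders can, which makes them the
#' augmentation of choice for very small renders. With the defaults each
#' image yields the 8 views of the dihedral group (itself plus 7 copies).
#'
#' @param manifest A manifest data.frame with its `split` column filled.
#' @param images Named list of samples/pixel arrays keyed by manifest path.
#' @param rotations Subset of `0:3`, quarter-turns to apply.
#' @param flips Logical vector; `TRUE` adds a horizontally mirrored copy of
#'   each rotation.
#' @param split Which split to expand (never `"test"`).
#' @return The expanded manifest with the enlarged image list attached as
#'   `attr(, "images")`.
#' @export
expand_dihedral <- function(manifest, images, rotations = 0:3,
                            flips = c(FALSE, TRUE), split = "train") {
  if (identical(split, "test"))
    stop("the test split is never augmented", call. = FALSE)
  rot90cw <- function(px)
    aperm(px, c(2L, 1L, 3L))[, rev(seq_len(dim(px)[1L])), , drop = FALSE]
  rows0 <- manifest[manifest$split == split, , drop = FALSE]
  add <- NULL
  for (r in rotations) for (f in flips) {
    if (r == 0L && !f) next
    rows <- rows0
    rows$path <- sprintf("%s_r%d%s", rows$path, r, if (f) "m" else "")
    rows$origin <- "augmented"
    for (i in seq_len(nrow(rows))) {
      px <- images[[rows0$path[i]]]
      if (inherits(px, "image_sample")) px <- px$pixels
      if (r > 0L) for (k in seq_len(r)) px <- rot90cw(px)
      if (f) px <- px[, rev(seq_len(dim(px)[2L])), , drop = FALSE]
      images[[rows$path[i]]] <- px
    }
    add <- rbind(add, rows)
  }
  out <- rbind(manifest, add)
  rownames(out) <- NULL
  attr(out, "images") <- images
  out
}
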