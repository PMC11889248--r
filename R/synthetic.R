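# Seeded synthetic micronucleus microscopy images.
#
# The generator emulates single-cell crops of a Giemsa-type slide scan as a
# stand-in for proprietary assay data: a bright nucleus ellipse on a darker
# cytoplasm/background, and — in the positive class — one or more small
# satellite chromatin blobs (micronuclei) placed in a ring just outside the
# nucleus boundary. Geometry is sampled per image from a seeded RNG so every
# image is exactly reproducible from (spec, label, seed).

#' Specify the synthetic image distribution
#'
#' All lengths are fractions: nucleus semi-axes relative to the image side,
#' micronucleus radii relative to the nucleus minor semi-axis, and the
#' placement ring relative to the nucleus boundary radius along the
#' placement direction. Intensities live in `[0, 1]`.
#'
#' @param side Rendered square side in pixels. The default 64 keeps
#'   generation and training desk-fast; images are upscaled bilinearly to
#'   the network input at load time.
#' @param mode `"default"` for mildly noisy, blurred images; `"easy"` for a
#'   high-contrast, noise-free, blur-free variant whose signal a trivial
#'   blob-count heuristic already separates (used for learnability checks).
#' @param background Background intensity range.
#' @param nucleus_axis Major semi-axis range, as a fraction of `side`.
#' @param nucleus_aspect Minor/major axis ratio range.
#' @param nucleus_intensity Nucleus intensity range.
#' @param mn_count Integer range of micronuclei per positive image.
#' @param mn_radius Micronucleus radius range, as a fraction of the nucleus
#'   minor semi-axis.
#' @param mn_ring Micronucleus centre distance range, in units of the
#'   nucleus boundary radius along the placement angle (> 1 keeps the blob
#'   outside the nucleus).
#' @param noise_sd Additive Gaussian pixel noise standard deviation.
#' @param blur_sd Gaussian blur standard deviation in pixels (0 = sharp
#'   binary masks).
#' @return A `synthetic_image_spec` list.
#' @export
synthetic_image_spec <- function(side = 64L, mode = c("default", "easy"),
                                 background = NULL, nucleus_axis = c(0.16, 0.26),
                                 nucleus_aspect = c(0.7, 1.0),
                                 nucleus_intensity = NULL,
                                 mn_count = c(1L, 3L), mn_radius = c(0.1, 0.33),
                                 mn_ring = c(1.15, 1.6),
                                 noise_sd = NULL, blur_sd = NULL) {
  mode <- match.arg(mode)
  if (is.null(background)) background <- if (mode == "easy") c(0.02, 0.10) else c(0.05, 0.25)
  if (is.null(nucleus_intensity)) nucleus_intensity <- if (mode == "easy") c(0.80, 0.95) else c(0.65, 0.95)
  if (is.null(noise_sd)) noise_sd <- if (mode == "easy") 0 else 0.02
  if (is.null(blur_sd)) blur_sd <- if (mode == "easy") 0 else 0.7
  spec <- list(side = as.integer(side), mode = mode, background = background,
               nucleus_axis = nucleus_axis, nucleus_aspect = nucleus_aspect,
               nucleus_intensity = nucleus_intensity,
               mn_count = as.integer(mn_count), mn_radius = mn_radius,
               mn_ring = mn_ring, noise_sd = noise_sd, blur_sd = blur_sd)
  if (side < 16L) stop("side must be at least 16", call. = FALSE)
  rng_ok <- function(r) length(r) == 2L && r[1L] <= r[2L]
  if (!all(vapply(spec[c("background", "nucleus_axis", "nucleus_aspect",
                         "nucleus_intensity", "mn_radius", "mn_ring")],
                  rng_ok, TRUE)))
    stop("all ranges must be length-2 increasing", call. = FALSE)
  if (max(background) > 1 || max(nucleus_intensity) > 1 ||
      min(background) < 0 || min(nucleus_intensity) < 0)
    stop("intensity ranges must lie in [0, 1]", call. = FALSE)
  if (max(mn_radius) >= 1)
    stop("micronucleus radius must stay below the nucleus minor semi-axis",
         call. = FALSE)
  if (min(mn_ring) <= 1)
    stop("the placement ring must start outside the nucleus boundary (> 1)",
         call. = FALSE)
  structure(spec, class = "synthetic_image_spec")
}

# evaluate `code` (lazily, in the caller's frame) under a local seeded RNG
# without disturbing the caller's stream
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

runif1 <- function(r) runif(1L, r[1L], r[2L])

# sample all geometry for one image (no rendering)
.sample_geometry <- function(spec, label) {
  side <- spec$side
  centre <- side / 2 + runif(2L, -0.05, 0.05) * side
  a <- runif1(spec$nucleus_axis) * side
  b <- a * runif1(spec$nucleus_aspect)
  theta <- runif(1L, 0, pi)
  nuc_int <- runif1(spec$nucleus_intensity)
  bg <- runif1(spec$background)
  mn <- data.frame(cx = numeric(0), cy = numeric(0), r = numeric(0),
                   intensity = numeric(0))
  if (label == 1L) {
    n_mn <- sample(spec$mn_count[1L]:spec$mn_count[2L], 1L)
    for (i in seq_len(n_mn)) {
      placed <- FALSE
      for (try in seq_len(200L)) {
        phi <- runif(1L, 0, 2 * pi)
        psi <- phi - theta
        rb <- a * b / sqrt((b * cos(psi))^2 + (a * sin(psi))^2)
        dist <- runif1(spec$mn_ring) * rb
        # clip below at 1.2 px so every recorded blob rasterises to a
        # handful of pixels even at small render sides
        r <- max(runif1(spec$mn_radius) * b, 1.2)
        cx <- centre[1L] + dist * cos(phi)
        cy <- centre[2L] + dist * sin(phi)
        # the blob must sit strictly outside the nucleus boundary (with a
        # 1.5 px moat so the two chromatin bodies never merge) and fully
        # inside the image
        if (dist - r > rb + 1.5 &&
            cx - r >= 1 && cx + r <= side && cy - r >= 1 && cy + r <= side) {
          mn <- rbind(mn, data.frame(cx = cx, cy = cy, r = r,
                                     intensity = nuc_int))
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("spec error: the micronucleus placement ring does not fit inside the image",
             call. = FALSE)
    }
  }
  list(background = bg,
       nucleus = list(cx = centre[1L], cy = centre[2L], a = a, b = b,
                      theta = theta, intensity = nuc_int),
       micronuclei = mn, n_micronuclei = nrow(mn))
}

#' Pixel mask of the nucleus ellipse
#'
#' Recomputes, from a sample's geometry record, the exact binary mask used
#' at render time: TRUE where the rotated-ellipse equation is satisfied.
#'
#' @param geometry The `geometry` component of an [generate_cell_image()]
#'   sample.
#' @param side Image side in pixels.
#' @return A logical `side x side` matrix (rows = y, columns = x).
#' @export
nucleus_mask <- function(geometry, side) {
  g <- geometry$nucleus
  xs <- matrix(rep(seq_len(side), each = side), side)   # column index = x
  ys <- matrix(rep(seq_len(side), times = side), side)  # row index = y
  dx <- xs - g$cx
  dy <- ys - g$cy
  u <- (dx * cos(g$theta) + dy * sin(g$theta)) / g$a
  v <- (-dx * sin(g$theta) + dy * cos(g$theta)) / g$b
  u * u + v * v <= 1
}

.render_image <- function(spec, geom) {
  side <- spec$side
  img <- matrix(geom$background, side, side)
  img[nucleus_mask(geom, side)] <- geom$nucleus$intensity
  if (geom$n_micronuclei > 0L) {
    xs <- matrix(rep(seq_len(side), each = side), side)
    ys <- matrix(rep(seq_len(side), times = side), side)
    for (i in seq_len(geom$n_micronuclei)) {
      m <- geom$micronuclei[i, ]
      img[(xs - m$cx)^2 + (ys - m$cy)^2 <= m$r^2] <- m$intensity
    }
  }
  px <- array(img, c(side, side, 3L))
  if (spec$blur_sd > 0) px <- gaussian_blur(px, spec$blur_sd)
  if (spec$noise_sd > 0) px <- px + array(rnorm(length(px), sd = spec$noise_sd), dim(px))
  px[px < 0] <- 0; px[px > 1] <- 1
  px
}

#' Generate one labeled synthetic cell image
#'
#' Deterministic for a fixed `(spec, label, seed)`: two calls produce
#' bitwise-identical pixels. The full geometry record (nucleus ellipse and
#' micronucleus blobs) travels with the sample so tests can assert against
#' the exact rendered truth.
#'
#' @param spec A [synthetic_image_spec()].
#' @param label 0 (normal) or 1 (micronucleus present).
#' @param seed Integer seed for this image.
#' @param render Set FALSE to sample only the geometry (fast, for
#'   distributional checks).
#' @return An object of class `image_sample`: a list with `pixels`
#'   (`side x side x 3` array in `[0, 1]`, grayscale replicated to RGB),
#'   `label`, `seed` and `geometry`.
#' @export
generate_cell_image <- function(spec, label, seed, render = TRUE) {
  stopifnot(inherits(spec, "synthetic_image_spec"), label %in% c(0L, 1L))
  with_seed(seed, {
    geom <- .sample_geometry(spec, as.integer(label))
    px <- if (render) .render_image(spec, geom) else NULL
    structure(list(pixels = px, label = as.integer(label), seed = seed,
                   geometry = geom, origin = "raw"),
              class = "image_sample")
  })
}

#' Generate a labeled synthetic dataset with controlled imbalance
#'
#' Draws exactly `round(n_total * positive_fraction)` positive samples (the
#' default 0.065 emulates the raw micronucleus prevalence of an unaugmented
#' assay test pool), shuffles the order, and returns samples plus a manifest.
#' Per-image seeds derive from `seed`, so the whole dataset is reproducible.
#'
#' @param n_total Total number of images (>= 2).
#' @param positive_fraction Fraction of positive (micronucleus) images,
#'   strictly inside (0, 1).
#' @param spec A [synthetic_image_spec()].
#' @param seed Dataset seed.
#' @param dir Optional directory; when given every image is written as PNG
#'   and the manifest paths point at the files, otherwise paths are symbolic
#'   `mem:` keys into the returned sample list.
#' @return A list with `samples` (named by path) and `manifest` (data.frame
#'   with columns path, label, split, origin, seed).
#' @export
generate_dataset <- function(n_total, positive_fraction = 0.065,
                             spec = synthetic_image_spec(), seed = 1L,
                             dir = NULL) {
  if (n_total < 2L) stop("n_total must be at least 2", call. = FALSE)
  if (positive_fraction <= 0 || positive_fraction >= 1)
    stop("positive_fraction must be strictly inside (0, 1)", call. = FALSE)
  n_pos <- round(n_total * positive_fraction)
  out <- with_seed(seed, {
    labels <- sample(c(rep(1L, n_pos), rep(0L, n_total - n_pos)))
    seeds <- sample.int(.Machine$integer.max - 1L, n_total)
    list(labels = labels, seeds = seeds)
  })
  paths <- if (is.null(dir)) sprintf("mem:s%d:%05d.png", seed, seq_len(n_total))
           else file.path(dir, sprintf("img_%05d.png", seq_len(n_total)))
  samples <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    s <- generate_cell_image(spec, out$labels[i], out$seeds[i])
    if (!is.null(dir)) png::writePNG(s$pixels, paths[i])
    samples[[i]] <- s
  }
  names(samples) <- paths
  manifest <- data.frame(path = paths, label = out$labels,
                         split = NA_character_, origin = "raw",
                         seed = out$seeds, stringsAsFactors = FALSE)
  list(samples = samples, manifest = manifest)
}

# 8-connected component labelling of a logical matrix (flood fill)
label_components <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  idx <- which(mask)
  for (p in idx) {
    if (lab[p] != 0L) next
    cur <- cur + 1L
    queue <- p
    lab[p] <- cur
    while (length(queue)) {
      q <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- (q - 1L) %% H + 1L
      cc <- (q - 1L) %/% H + 1L
      for (dr in -1:1) for (dc in -1:1) {
        rr <- r + dr; cc2 <- cc + dc
        if (rr >= 1L && rr <= H && cc2 >= 1L && cc2 <= W) {
          qq <- (cc2 - 1L) * H + rr
          if (mask[qq] && lab[qq] == 0L) {
            lab[qq] <- cur
            queue <- c(queue, qq)
          }
        }
      }
    }
  }
  lab
}

#' Trivial luminance-and-blob-count heuristic classifier
#'
#' A deliberately simple baseline used to certify that the synthetic signal
#' is learnable: threshold the image midway between background and nucleus
#' intensity, label connected bright components, and call the image positive
#' when more than one non-trivial component remains (nucleus plus at least
#' one satellite blob).
#'
#' @param pixels An `(H, W, 3)` image in `[0, 1]` or an `image_sample`.
#' @param min_blob Minimum component area in pixels to count as a blob.
#' @return Predicted label, 0 or 1.
#' @export
blob_count_classifier <- function(pixels, min_blob = 3L) {
  if (inherits(pixels, "image_sample")) pixels <- pixels$pixels
  gray <- (pixels[, , 1L] + pixels[, , 2L] + pixels[, , 3L]) / 3
  thr <- (stats::median(gray) + max(gray)) / 2
  lab <- label_components(gray > thr)
  sizes <- tabulate(lab[lab > 0L])
  as.integer(sum(sizes >= min_blob) >= 2L)
}
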