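#' Construct a feature map
#'
#' A feature map is the tensor flowing through every block of the network: a
#' channel-major, rank-3 numeric array indexed `(channel, row, column)`. The
#' constructor validates the layout contract (all dimensions at least 1, all
#' values finite) and returns the array unchanged otherwise.
#'
#' @param values A numeric 3-D array `(C, H, W)`, or a matrix which is treated
#'   as a single-channel map.
#' @return A validated `(C, H, W)` array.
#' @examples
#' x <- feature_map(array(rnorm(4 * 8 * 8), c(4, 8, 8)))
#' dim(x)
#' @export
feature_map <- function(values) {
  if (is.matrix(values)) values <- array(values, c(1L, dim(values)))
  .check_fmap(values, "values")
  values
}

#' Cut a feature map into patch-token sequences
#'
#' Divides a `(C, H, W)` feature map into non-overlapping `ph x pw` patches
#' and rearranges it into sequence form: `(H/ph) * (W/pw)` patches, each
#' holding `ph * pw` tokens of dimension `C`. This is the unfold step feeding
#' the transformer stage of a MobileViT block; [fold_patches()] is its exact
#' inverse. Non-divisible spatial dimensions are rejected rather than padded
#' so that fold(unfold(x)) is always the identity.
#'
#' @param x A `(C, H, W)` feature map.
#' @param ph,pw Patch height and width; must divide `H` and `W`.
#' @return An object of class `patch_sequence`: a list with `tokens`, an
#'   array `(C, ph*pw, n_patches)` (token position within patch, then patch
#'   index in column-major patch-grid order), and the geometry needed to fold
#'   back.
#' @examples
#' x <- feature_map(array(seq_len(3 * 4 * 4), c(3, 4, 4)))
#' s <- unfold_patches(x, 2, 2)
#' dim(s$tokens)                          # 3 x 4 x 4
#' all.equal(fold_patches(s), x)          # exact round trip
#' @export
unfold_patches <- function(x, ph, pw) {
  .check_fmap(x)
  d <- dim(x)
  C <- d[1L]; H <- d[2L]; W <- d[3L]
  if (H %% ph != 0L || W %% pw != 0L)
    stop(sprintf("patch size %dx%d does not divide feature map %dx%d", ph, pw, H, W),
         call. = FALSE)
  tokens <- unfold4(array(x, c(d, 1L)), ph, pw)
  dim(tokens) <- dim(tokens)[1:3]
  structure(list(tokens = tokens, H = H, W = W, ph = ph, pw = pw),
            class = "patch_sequence")
}

#' Reassemble a feature map from a patch-token sequence
#'
#' Exact inverse of [unfold_patches()].
#'
#' @param seq A `patch_sequence`, or a bare `(C, ph*pw, n_patches)` token
#'   array (then the geometry arguments are required).
#' @param H,W,ph,pw Geometry of the original map; taken from `seq` when it is
#'   a `patch_sequence`.
#' @return The reconstructed `(C, H, W)` feature map.
#' @export
fold_patches <- function(seq, H = NULL, W = NULL, ph = NULL, pw = NULL) {
  if (inherits(seq, "patch_sequence")) {
    tokens <- seq$tokens
    H <- seq$H; W <- seq$W; ph <- seq$ph; pw <- seq$pw
  } else {
    tokens <- seq
    if (is.null(H) || is.null(W) || is.null(ph) || is.null(pw))
      stop("H, W, ph, pw are required when folding a bare token array", call. = FALSE)
  }
  d <- dim(tokens)
  if (length(d) != 3L || d[2L] != ph * pw || d[3L] != (H %/% ph) * (W %/% pw))
    stop("token array shape is inconsistent with (H, W, ph, pw)", call. = FALSE)
  if (H %% ph != 0L || W %% pw != 0L)
    stop("patch size does not divide the target dimensions", call. = FALSE)
  x <- fold4(array(tokens, c(d, 1L)), H, W, ph, pw)
  array(x, dim(x)[1:3])
}

# Batched unfold: (C,H,W,N) -> (C, ph*pw, Np, N).
# Patch index runs column-major over the (H/ph) x (W/pw) patch grid; token
# index runs column-major inside each patch.
unfold4 <- function(x, ph, pw) {
  d <- dim(x)
  C <- d[1L]; H <- d[2L]; W <- d[3L]; N <- d[4L]
  nh <- H %/% ph; nw <- W %/% pw
  dim(x) <- c(C, ph, nh, pw, nw, N)
  x <- aperm(x, c(1L, 2L, 4L, 3L, 5L, 6L))
  dim(x) <- c(C, ph * pw, nh * nw, N)
  x
}

fold4 <- function(tokens, H, W, ph, pw) {
  d <- dim(tokens)
  C <- d[1L]; N <- d[4L]
  nh <- H %/% ph; nw <- W %/% pw
  dim(tokens) <- c(C, ph, pw, nh, nw, N)
  x <- aperm(tokens, c(1L, 2L, 4L, 3L, 5L, 6L))
  dim(x) <- c(C, H, W, N)
  x
}
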