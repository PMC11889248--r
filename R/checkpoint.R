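# Checkpoints and transfer-learning weight loading. A checkpoint is the
# flat named state of the module tree (trainable parameters plus
# normalisation running statistics, keyed by path) serialized with saveRDS,
# with a JSON sidecar carrying the variant configuration and a content hash.

#' Save / load a model checkpoint
#'
#' @param model An `mnvit` model.
#' @param path Destination file; a JSON sidecar is written at
#'   `paste0(path, ".json")`.
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns a list with `params` (flat named state) and `config`.
#' @export
save_checkpoint <- function(model, path) {
  state <- collect_params(model$net, buffers = TRUE)
  obj <- list(params = state, config = unclass(model$config))
  saveRDS(obj, path)
  sidecar <- list(config = unclass(model$config),
                  n_tensors = length(state),
                  n_parameters = count_parameters(model),
                  hash = digest::digest(state))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path))
    stop("checkpoint not found: ", path, call. = FALSE)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("unreadable checkpoint: ", path, " (", conditionMessage(e), ")",
         call. = FALSE))
  if (!is.list(obj) || is.null(obj$params))
    stop("corrupt checkpoint: ", path, call. = FALSE)
  obj
}

#' Load pretrained weights into a model
#'
#' Transfer-learning initialisation: copies every checkpoint tensor whose
#' path and shape match the target model, skips (and reports) the rest, and
#' optionally reinitialises the classification head — the standard recipe
#' when moving a backbone pretrained on a wide source domain to a two-class
#' task head.
#'
#' @param model An `mnvit` model (modified in place; environments are
#'   shared).
#' @param checkpoint A path or the object returned by [load_checkpoint()].
#' @param exclude_head Reinitialise the classifier instead of copying it.
#' @return An object of class `transfer_report`: counts of `matched`,
#'   `skipped` and `reinitialized` tensors plus a `detail` data.frame.
#' @export
load_pretrained <- function(model, checkpoint, exclude_head = TRUE) {
  if (is.character(checkpoint)) checkpoint <- load_checkpoint(checkpoint)
  src <- checkpoint$params
  tgt <- collect_params(model$net, buffers = TRUE)
  head_keys <- grep("^head/classifier", names(tgt), value = TRUE)
  status <- character(0); keys <- character(0)
  accepted <- list()
  for (nm in names(src)) {
    keys <- c(keys, nm)
    if (exclude_head && nm %in% head_keys) {
      status <- c(status, "head")
    } else if (is.null(tgt[[nm]])) {
      status <- c(status, "skipped: no matching tensor")
    } else if (!identical(dim(tgt[[nm]]), dim(src[[nm]])) ||
               length(tgt[[nm]]) != length(src[[nm]])) {
      status <- c(status, "skipped: shape mismatch")
    } else {
      accepted[[nm]] <- src[[nm]]
      status <- c(status, "matched")
    }
  }
  assign_params(model$net, accepted)
  reinit <- 0L
  if (exclude_head) {
    walk_modules(model$net, function(mod, path) {
      if (path == "head/classifier") {
        mod$par$w <- matrix(rnorm(length(mod$par$w), sd = 0.01),
                            nrow(mod$par$w), ncol(mod$par$w))
        if (!is.null(mod$par$b)) mod$par$b <- 0 * mod$par$b
        reinit <<- length(mod$par)
      }
    })
  }
  detail <- data.frame(tensor = keys, status = status, stringsAsFactors = FALSE)
  structure(list(matched = sum(status == "matched"),
                 skipped = sum(startsWith(status, "skipped")),
                 reinitialized = reinit,
                 detail = detail),
            class = "transfer_report")
}

#' @export
print.transfer_report <- function(x, ...) {
  cat(sprintf("transfer: %d tensors matched, %d skipped, %d head tensors reinitialized\n",
              x$matched, x$skipped, x$reinitialized))
  sk <- x$detail[startsWith(x$detail$status, "skipped"), , drop = FALSE]
  if (nrow(sk)) {
    cat("skipped tensors:\n")
    for (i in seq_len(min(10L, nrow(sk))))
      cat(sprintf("  %s (%s)\n", sk$tensor[i], sk$status[i]))
    if (nrow(sk) > 10L) cat(sprintf("  ... and %d more\n", nrow(sk) - 10L))
  }
  invisible(x)
}
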