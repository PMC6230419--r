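# Single-file checkpoint: a serialized list holding a JSON-compatible header
# (format tag, architecture hash, class names, normalization convention,
# training config/seed) and the named parameter arrays keyed by layer name.
# Save/load round trips are bit-exact.

# small deterministic FNV-1a hash over a string; keys checkpoints to the
# architecture that produced them without an external digest dependency.
# State is kept as a double in [0, 2^32); the XOR touches only the low byte
# and the modular multiply is split into 16-bit halves to stay inside the
# exact-integer range of doubles.
fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    h1 <- h %/% 65536; h0 <- h %% 65536
    h <- (h0 * p + ((h1 * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

architecture_hash <- function(arch) {
  desc <- vapply(arch$layers, function(l)
    paste(l$name, l$type, l$in_channels %||% "", l$out_channels %||% "",
          l$channels %||% "", l$source %||% "", sep = ":"),
    character(1))
  fnv1a(paste(desc, collapse = "|"))
}

#' Save a trained model to a single checkpoint file
#'
#' @param object a fitted [segnet()] model.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
save_segnet <- function(object, path) {
  stopifnot(inherits(object, "segnet"))
  header <- list(format = "brainseg-checkpoint", version = 1L,
                 architecture_hash = architecture_hash(object$arch),
                 filter_width = object$arch$filter_width,
                 classes = object$arch$classes,
                 normalization = "zero-center",
                 class_weights = as.list(object$class_weights),
                 seed = object$config$seed)
  header_json <- as.character(jsonlite::toJSON(header, auto_unbox = TRUE,
                                               digits = NA))
  saveRDS(list(header_json = header_json, params = object$params,
               history = object$history, config = object$config,
               arch = object$arch), path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' Verifies the format tag and that the stored architecture hash matches the
#' architecture rebuilt from the header's filter width; a mismatch is
#' rejected.
#'
#' @param path a file written by [save_segnet()].
#' @return the restored `segnet` object.
#' @export
load_segnet <- function(path) {
  ck <- readRDS(path)
  header <- tryCatch(jsonlite::fromJSON(ck$header_json),
                     error = function(e) NULL)
  if (!identical(header$format, "brainseg-checkpoint"))
    stop("not a brainseg checkpoint: ", path)
  arch <- ck$arch
  if (!identical(architecture_hash(arch), header$architecture_hash))
    stop("checkpoint architecture hash mismatch; refusing to load")
  structure(list(params = ck$params, arch = arch, history = ck$history,
                 class_weights = unlist(header$class_weights),
                 config = ck$config, call = NULL),
            class = "segnet")
}
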