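# The 31-layer compact SegNet: two encoders (conv-bn-relu x2, maxpool) and two
# mirrored decoders (unpool, conv-bn-relu x2), a 4-channel scoring convolution
# inside decoder1, pixelwise softmax, and a class-weighted pixel
# classification head. encoder1's pool indices feed decoder1's unpool and
# encoder2's feed decoder2's.

#' Build the 31-layer network architecture
#'
#' Returns the ordered layer list of the compact two-encoder/two-decoder
#' SegNet: every convolution is 3x3, stride 1, same padding; both poolings are
#' 2x2 stride 2 with memorized argmax indices; the two unpoolings consume the
#' indices of their paired encoder pool (encoder1 <-> decoder1,
#' encoder2 <-> decoder2). The final convolution maps to 4 channels, one per
#' class (background, CSF, GM, WM).
#'
#' @param filter_width number of filters in the hidden convolutions. The
#'   default 64 is the reference network; smaller values give fast reduced
#'   networks for testing and keep every shape relation intact.
#' @return an `architecture` object: list of 31 layer descriptors plus the
#'   pool/unpool pairings and the class names.
#' @export
build_architecture <- function(filter_width = 64L) {
  fw <- as.integer(filter_width)
  stopifnot(fw >= 1L)
  conv <- function(name, ci, co) list(name = name, type = "conv",
                                      in_channels = ci, out_channels = co)
  bn <- function(name, ch) list(name = name, type = "bn", channels = ch)
  rl <- function(name) list(name = name, type = "relu")
  layers <- list(
    list(name = "input", type = "input"),
    conv("encoder1_conv1", 1L, fw), bn("encoder1_bn_1", fw), rl("encoder1_relu_1"),
    conv("encoder1_conv2", fw, fw), bn("encoder1_bn_2", fw), rl("encoder1_relu_2"),
    list(name = "encoder1_maxpool", type = "maxpool"),
    conv("encoder2_conv1", fw, fw), bn("encoder2_bn_1", fw), rl("encoder2_relu_1"),
    conv("encoder2_conv2", fw, fw), bn("encoder2_bn_2", fw), rl("encoder2_relu_2"),
    list(name = "encoder2_maxpool", type = "maxpool"),
    list(name = "decoder2_unpool", type = "unpool", source = "encoder2_maxpool"),
    conv("decoder2_conv2", fw, fw), bn("decoder2_bn_2", fw), rl("decoder2_relu_2"),
    conv("decoder2_conv1", fw, fw), bn("decoder2_bn_1", fw), rl("decoder2_relu_1"),
    list(name = "decoder1_unpool", type = "unpool", source = "encoder1_maxpool"),
    conv("decoder1_conv2", fw, fw), bn("decoder1_bn_2", fw), rl("decoder1_relu_2"),
    conv("decoder1_conv1", fw, 4L), bn("decoder1_bn_1", 4L), rl("decoder1_relu_1"),
    list(name = "softmax", type = "softmax"),
    list(name = "pixel_classify", type = "pixel_classification")
  )
  structure(list(
    layers = layers,
    filter_width = fw,
    pairings = c(encoder1_maxpool = "decoder1_unpool",
                 encoder2_maxpool = "decoder2_unpool"),
    classes = c("background", "CSF", "GM", "WM")
  ), class = "architecture")
}

#' @export
print.architecture <- function(x, ...) {
  cat(sprintf("compact SegNet architecture: %d layers, filter width %d\n",
              length(x$layers), x$filter_width))
  for (i in seq_along(x$layers)) {
    l <- x$layers[[i]]
    extra <- switch(l$type,
      conv = sprintf(" (%d x 3 x 3 x %d)", l$out_channels, l$in_channels),
      bn = sprintf(" (%d channels)", l$channels),
      unpool = sprintf(" (indices from %s)", l$source),
      "")
    cat(sprintf("  %2d %-18s %s%s\n", i, l$name, l$type, extra))
  }
  invisible(x)
}

#' Initialize network parameters
#'
#' Convolution weights are drawn from a zero-mean Gaussian with fan-in scaled
#' variance `2 / (9 * in_channels)` (He initialization, appropriate for ReLU
#' stacks); biases start at zero; batch-norm scale/shift at one/zero with
#' reset running statistics.
#'
#' @param arch an [build_architecture()] object.
#' @param seed integer seed making the draw reproducible.
#' @return a `network_params` object: named list keyed by layer name.
#' @export
init_params <- function(arch, seed = 1L) {
  set.seed(seed)
  params <- list()
  for (l in arch$layers) {
    if (l$type == "conv") {
      sd <- sqrt(2 / (9 * l$in_channels))
      params[[l$name]] <- list(
        W = array(stats::rnorm(l$out_channels * l$in_channels * 9, 0, sd),
                  c(l$out_channels, l$in_channels, 3L, 3L)),
        b = rep(0, l$out_channels))
    } else if (l$type == "bn") {
      params[[l$name]] <- bn_params(l$channels)
    }
  }
  structure(params, class = "network_params", architecture = arch)
}

#' Count trainable scalars
#'
#' Convolution kernels and biases plus batch-norm scale and shift; running
#' statistics are state, not trainable parameters. The full-width reference
#' network has 225,420.
#'
#' @param params a [init_params()] object.
#' @return integer count.
#' @export
count_trainable <- function(params) {
  n <- 0L
  for (p in params) {
    if (!is.null(p$W)) n <- n + length(p$W) + length(p$b)
    else if (inherits(p, "bn_params")) n <- n + length(p$gamma) + length(p$beta)
  }
  n
}

# Flat view of trainable parameters, used by the optimizer and gradient checks.
trainable_list <- function(params) {
  out <- list()
  for (nm in names(params)) {
    p <- params[[nm]]
    if (!is.null(p$W)) {
      out[[paste0(nm, "/W")]] <- p$W
      out[[paste0(nm, "/b")]] <- p$b
    } else if (inherits(p, "bn_params")) {
      out[[paste0(nm, "/gamma")]] <- p$gamma
      out[[paste0(nm, "/beta")]] <- p$beta
    }
  }
  out
}

set_trainable <- function(params, flat) {
  for (nm in names(flat)) {
    parts <- strsplit(nm, "/", fixed = TRUE)[[1L]]
    layer <- parts[1L]; field <- parts[2L]
    slot <- switch(field, W = "W", b = "b", gamma = "gamma", beta = "beta")
    old <- params[[layer]][[slot]]
    params[[layer]][[slot]] <- if (is.array(old)) array(flat[[nm]], dim(old)) else as.numeric(flat[[nm]])
  }
  params
}

#' Forward pass of the network
#'
#' Runs the full 31-layer stack. Input spatial dimensions must be divisible
#' by 4 so the two 2x pool/unpool pairs invert cleanly.
#'
#' @param params a [init_params()] (or trained) parameter set.
#' @param arch the matching architecture.
#' @param x rank-4 input tensor with one channel.
#' @param mode `"train"` uses minibatch statistics in batch norm (and updates
#'   the running statistics in the returned `params`); `"infer"` uses the
#'   stored running statistics and mutates nothing.
#' @param keep_cache keep the intermediates needed by the backward pass.
#' @return list with `probs` (tensor `(batch, 4, height, width)` of per-pixel
#'   class probabilities), `params` (updated running statistics in train
#'   mode), and `cache` when requested.
#' @export
segnet_forward <- function(params, arch, x, mode = c("train", "infer"),
                           keep_cache = FALSE) {
  mode <- match.arg(mode)
  d <- check_tensor(x)
  if (d[2L] != 1L) stop("network input must have exactly one channel")
  if (d[3L] %% 4L != 0L || d[4L] %% 4L != 0L)
    stop(sprintf("input spatial dimensions must be divisible by 4, got %d x %d",
                 d[3L], d[4L]))
  cache <- list()
  pool_store <- list()
  cur <- x
  for (l in arch$layers) {
    if (l$type == "input" || l$type == "pixel_classification") next
    if (l$type == "conv") {
      if (keep_cache) cache[[l$name]] <- list(input = cur)
      cur <- conv2d_3x3_same(cur, params[[l$name]]$W, params[[l$name]]$b)
    } else if (l$type == "bn") {
      r <- batch_norm(cur, params[[l$name]], mode, want_cache = keep_cache)
      params[[l$name]] <- r$params
      if (keep_cache) cache[[l$name]] <- r$cache
      cur <- r$values
    } else if (l$type == "relu") {
      if (keep_cache) cache[[l$name]] <- list(mask = cur > 0)
      cur <- relu(cur)
    } else if (l$type == "maxpool") {
      r <- maxpool2x2_with_indices(cur)
      pool_store[[l$name]] <- list(indices = r$indices, in_dim = dim(cur))
      cur <- r$values
    } else if (l$type == "unpool") {
      src <- pool_store[[l$source]]
      if (is.null(src)) stop("unpool before its paired pool ran")
      cur <- maxunpool2x2(cur, src$indices, src$in_dim[3:4])
    } else if (l$type == "softmax") {
      if (keep_cache) cache[["softmax_input"]] <- cur
      cur <- softmax_pixelwise(cur)
    }
  }
  out <- list(probs = cur, params = params)
  if (keep_cache) {
    cache$pools <- pool_store
    out$cache <- cache
  }
  out
}

# Backward pass: dscores is the gradient of the loss w.r.t. the softmax input
# (the combined softmax + cross-entropy gradient computed by the loss module).
# Returns a flat named gradient list congruent with trainable_list().
segnet_backward <- function(params, arch, cache, dscores) {
  grads <- list()
  cur <- dscores
  layers <- arch$layers
  for (i in rev(seq_along(layers))) {
    l <- layers[[i]]
    if (l$type %in% c("input", "pixel_classification", "softmax")) next
    if (l$type == "relu") {
      cur <- cur * cache[[l$name]]$mask
    } else if (l$type == "bn") {
      r <- batch_norm_backward(cur, params[[l$name]], cache[[l$name]])
      grads[[paste0(l$name, "/gamma")]] <- r$dgamma
      grads[[paste0(l$name, "/beta")]] <- r$dbeta
      cur <- r$dx
    } else if (l$type == "conv") {
      r <- conv2d_backward(cache[[l$name]]$input, params[[l$name]]$W, cur)
      grads[[paste0(l$name, "/W")]] <- r$dW
      grads[[paste0(l$name, "/b")]] <- r$db
      cur <- r$dx
    } else if (l$type == "maxpool") {
      src <- cache$pools[[l$name]]
      cur <- .maxunpool_cpp(cur, as.integer(dim(cur)), src$indices,
                            as.integer(src$in_dim[3L]), as.integer(src$in_dim[4L]))
    } else if (l$type == "unpool") {
      src <- cache$pools[[l$source]]
      pooled_dim <- dim(cur) / c(1L, 1L, 2L, 2L)
      cur <- .unpool_backward_cpp(cur, as.integer(dim(cur)), src$indices,
                                  as.integer(pooled_dim))
    }
  }
  grads
}
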