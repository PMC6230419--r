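#' @useDynLib brainseg, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# ---- tensor helpers ---------------------------------------------------------

#' Construct a rank-4 tensor in (batch, channel, height, width) order
#'
#' All network layers exchange rank-4 numeric arrays with dimensions
#' `(batch, channel, height, width)`. This helper promotes a single 2D slice
#' (or a list of slices) to that layout.
#'
#' @param x a numeric matrix (one slice), or a list of equally sized matrices.
#' @return a numeric array with `dim = c(batch, 1, height, width)`.
#' @export
as_tensor <- function(x) {
  if (is.matrix(x)) x <- list(x)
  stopifnot(length(x) >= 1L, all(vapply(x, is.matrix, logical(1))))
  d <- dim(x[[1L]])
  n <- length(x)
  out <- array(0, c(n, 1L, d[1L], d[2L]))
  for (i in seq_len(n)) {
    if (!identical(dim(x[[i]]), d)) stop("all slices must share one shape")
    out[i, 1L, , ] <- x[[i]]
  }
  out
}

check_tensor <- function(x) {
  if (!is.array(x) || length(dim(x)) != 4L)
    stop("expected a rank-4 (batch, channel, height, width) array")
  invisible(dim(x))
}

# ---- convolution ------------------------------------------------------------

#' 3x3 same-padding convolution
#'
#' Stride-1 convolution with a one-pixel zero border so spatial dimensions are
#' preserved, the only convolution shape the network uses.
#'
#' @param x rank-4 input tensor `(batch, in_channels, height, width)`.
#' @param kernels weight array `(out_channels, in_channels, 3, 3)`.
#' @param bias numeric vector of length `out_channels`.
#' @return rank-4 tensor `(batch, out_channels, height, width)`.
#' @export
conv2d_3x3_same <- function(x, kernels, bias) {
  d <- check_tensor(x)
  kd <- dim(kernels)
  if (length(kd) != 4L || kd[3L] != 3L || kd[4L] != 3L)
    stop("kernels must have shape (out_channels, in_channels, 3, 3)")
  if (kd[2L] != d[2L])
    stop(sprintf("channel mismatch: input has %d channels, kernels expect %d",
                 d[2L], kd[2L]))
  if (length(bias) != kd[1L]) stop("bias length must equal out_channels")
  .conv2d_forward_cpp(x, as.integer(d), kernels, kd[1L], kd[2L], as.numeric(bias))
}

conv2d_backward <- function(x, kernels, dy) {
  d <- check_tensor(x)
  kd <- dim(kernels)
  .conv2d_backward_cpp(x, as.integer(d), kernels, kd[1L], kd[2L], dy)
}

# ---- batch normalization ----------------------------------------------------

#' Create batch-normalization parameters
#'
#' @param channels number of feature channels normalized independently.
#' @param eps variance floor added before the square root.
#' @param momentum exponential-moving-average factor for the running
#'   statistics (`running <- (1 - momentum) * running + momentum * batch`).
#' @return a `bn_params` list with unit scale, zero shift and reset running
#'   statistics.
#' @export
bn_params <- function(channels, eps = 1e-5, momentum = 0.1) {
  structure(list(
    gamma = rep(1, channels), beta = rep(0, channels),
    running_mean = rep(0, channels), running_var = rep(1, channels),
    eps = eps, momentum = momentum, n_updates = 0L
  ), class = "bn_params")
}

# reshape (N,C,H,W) so each column is one channel's N*H*W values
channel_matrix <- function(x) {
  d <- dim(x)
  matrix(aperm(x, c(1L, 3L, 4L, 2L)), ncol = d[2L])
}

channel_unmatrix <- function(m, d) {
  aperm(array(m, c(d[1L], d[3L], d[4L], d[2L])), c(1L, 4L, 2L, 3L))
}

#' Batch normalization over a minibatch
#'
#' In `"train"` mode each channel is normalized by its minibatch mean and
#' (biased) variance taken over batch and spatial positions, then scaled and
#' shifted; running statistics are updated by an exponential moving average.
#' In `"infer"` mode the stored running statistics are used instead, which
#' requires that at least one training update has happened.
#'
#' @param x rank-4 input tensor.
#' @param params a [bn_params()] object with matching channel count.
#' @param mode `"train"` or `"infer"`.
#' @param want_cache also return the intermediates the backward pass needs.
#' @return list with `values` (normalized tensor), `params` (with updated
#'   running statistics in train mode) and `cache` (intermediates consumed by
#'   the backward pass, when requested).
#' @export
batch_norm <- function(x, params, mode = c("train", "infer"),
                       want_cache = TRUE) {
  mode <- match.arg(mode)
  d <- check_tensor(x)
  C <- d[2L]
  if (length(params$gamma) != C)
    stop(sprintf("batch norm expects %d channels, input has %d",
                 length(params$gamma), C))
  if (mode == "train") {
    st <- .bn_stats_cpp(x, as.integer(d))
    mu <- st$mean
    v <- st$var
    params$running_mean <- (1 - params$momentum) * params$running_mean +
      params$momentum * mu
    params$running_var <- (1 - params$momentum) * params$running_var +
      params$momentum * v
    params$n_updates <- params$n_updates + 1L
  } else {
    if (params$n_updates == 0L)
      stop("batch norm inference requested before any running statistics exist")
    mu <- params$running_mean
    v <- params$running_var
  }
  invstd <- 1 / sqrt(v + params$eps)
  ap <- .bn_apply_cpp(x, as.integer(d), mu, invstd, params$gamma, params$beta,
                      want_cache)
  out <- list(values = ap$y, params = params)
  if (want_cache)
    out$cache <- list(xhat = ap$xhat, invstd = invstd, dim = d, mode = mode)
  out
}

# dy: rank-4 gradient w.r.t. the bn output. Returns dx plus dgamma/dbeta.
# Train-mode formula accounts for the dependence of the batch statistics on x.
batch_norm_backward <- function(dy, params, cache) {
  r <- .bn_backward_cpp(dy, cache$xhat, as.integer(cache$dim), params$gamma,
                        cache$invstd, cache$mode == "train")
  list(dx = r$dx, dgamma = r$dgamma, dbeta = r$dbeta)
}

# ---- simple elementwise layers ----------------------------------------------

#' Rectified linear activation
#'
#' @param x numeric array.
#' @return `max(0, x)` elementwise.
#' @export
relu <- function(x) {
  x[x < 0] <- 0
  x
}

# ---- pooling / unpooling -----------------------------------------------------

#' 2x2 stride-2 max pooling with memorized argmax indices
#'
#' Halves both spatial dimensions with non-overlapping 2x2 windows. Alongside
#' the pooled values it returns, for every output position, the flat position
#' (1-based, column-major with rows fastest) of the window maximum in the
#' input plane. Ties keep the first maximum in row-major window order, so a
#' constant window memorizes its top-left corner.
#'
#' @param x rank-4 tensor with even height and width.
#' @return list with `values` (pooled tensor) and `indices` (integer array of
#'   the same shape as `values`).
#' @export
maxpool2x2_with_indices <- function(x) {
  d <- check_tensor(x)
  .maxpool_forward_cpp(x, as.integer(d))
}

#' Max unpooling with memorized indices
#'
#' Sparse inverse of [maxpool2x2_with_indices()]: each pooled value is written
#' back at its memorized argmax position; all other entries are exactly zero.
#'
#' @param x rank-4 pooled tensor.
#' @param indices the index array produced by the paired max pool.
#' @param out_dim spatial dimensions `c(height, width)` of the unpooled
#'   output, i.e. of the original pool input.
#' @return rank-4 tensor of spatial size `out_dim`.
#' @export
maxunpool2x2 <- function(x, indices, out_dim) {
  d <- check_tensor(x)
  if (!identical(dim(indices), dim(x)))
    stop("indices must have the same shape as the pooled tensor")
  .maxunpool_cpp(x, as.integer(d), indices, as.integer(out_dim[1L]),
                 as.integer(out_dim[2L]))
}

# ---- softmax / labels --------------------------------------------------------

#' Pixelwise softmax over the channel dimension
#'
#' Numerically stable (per-pixel maximum subtracted before exponentiation).
#'
#' @param x rank-4 tensor of class scores.
#' @return tensor of identical shape; along channels, values are nonnegative
#'   and sum to one at every pixel.
#' @export
softmax_pixelwise <- function(x) {
  d <- check_tensor(x)
  C <- d[2L]
  xm <- channel_matrix(x)            # rows = pixels, cols = channels
  xm <- xm - apply(xm, 1L, max)
  e <- exp(xm)
  channel_unmatrix(e / rowSums(e), d)
}

#' Per-pixel class decisions from channel probabilities
#'
#' @param probs rank-4 probability tensor with 4 channels.
#' @return a list of integer label matrices (values 0-3), one per batch item.
#'   Ties resolve to the lowest class index, so all-equal channels decode to
#'   background.
#' @export
predict_labels <- function(probs) {
  d <- check_tensor(probs)
  pm <- channel_matrix(probs)
  lab <- max.col(pm, ties.method = "first") - 1L
  arr <- array(lab, c(d[1L], d[3L], d[4L]))
  lapply(seq_len(d[1L]), function(n) matrix(arr[n, , ], d[3L], d[4L]))
}
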