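# Training environment: median-frequency class weighting, class-weighted
# cross-entropy and its gradient, on-the-fly augmentation (random X-axis
# reflection + rotation within +/-10 degrees), stochastic gradient descent
# with momentum, and the minibatch epoch loop.

#' Median-frequency-balanced class weights
#'
#' For class frequencies `f_c` over all pixels of all label maps, the
#' median-frequency scheme assigns `w_c = median(f) / f_c`, damping the
#' dominant background and boosting rare tissue. The uniform scheme returns
#' unit weights.
#'
#' @param labels a label matrix or list of label matrices covering every
#'   class at least once (weights are undefined for an absent class).
#' @param scheme `"median-frequency"` or `"uniform"`.
#' @return named numeric vector of 4 positive weights.
#' @export
compute_class_weights <- function(labels, scheme = c("median-frequency", "uniform")) {
  scheme <- match.arg(scheme)
  freq <- class_frequencies(labels)
  if (scheme == "uniform")
    return(stats::setNames(rep(1, 4), names(freq)))
  if (any(freq == 0))
    stop("class(es) absent from the labels, weights undefined: ",
         paste(names(freq)[freq == 0], collapse = ", "))
  stats::median(freq) / freq
}

#' Class-weighted cross-entropy loss
#'
#' `loss = -(1/N_pixels) * sum_p w[y(p)] * log(max(probs[y(p)](p), floor))`
#' where the sum runs over every pixel of the batch and `N_pixels` is the
#' total pixel count (normalization is by pixels, not by summed weights, so
#' the learning-rate scale is independent of the weight scheme).
#'
#' @param probs rank-4 probability tensor `(batch, 4, height, width)`.
#' @param truth a label matrix or list of label matrices, one per batch item.
#' @param weights numeric vector of 4 class weights.
#' @param floor probability floor applied before the logarithm.
#' @return scalar loss.
#' @export
weighted_cross_entropy <- function(probs, truth, weights, floor = 1e-12) {
  d <- check_tensor(probs)
  if (is.matrix(truth)) truth <- list(truth)
  if (length(truth) != d[1L]) stop("batch size mismatch between probs and truth")
  y <- labels_to_array(truth, d)
  pm <- channel_matrix(probs)                 # rows: (n,h,w), cols: class
  yv <- as.integer(y) + 1L
  p_true <- pm[cbind(seq_along(yv), yv)]
  -mean(weights[yv] * log(pmax(p_true, floor)))
}

# stack list of HxW label matrices into (N,H,W) array matching tensor order
labels_to_array <- function(truth, d) {
  y <- array(0L, c(d[1L], d[3L], d[4L]))
  for (n in seq_along(truth)) {
    if (!identical(dim(truth[[n]]), d[3:4]))
      stop("label map shape does not match probability tensor")
    y[n, , ] <- truth[[n]]
  }
  y
}

# Gradient of the weighted cross-entropy w.r.t. the softmax *input* scores:
# d/ds_k = (1/N) * w[y] * (p_k - 1{k == y}).
wce_score_gradient <- function(probs, truth, weights) {
  d <- check_tensor(probs)
  if (is.matrix(truth)) truth <- list(truth)
  y <- labels_to_array(truth, d)
  pm <- channel_matrix(probs)
  yv <- as.integer(y) + 1L
  g <- pm
  g[cbind(seq_along(yv), yv)] <- g[cbind(seq_along(yv), yv)] - 1
  g <- g * (weights[yv] / length(yv))
  channel_unmatrix(g, d)
}

#' Loss and gradients for one minibatch
#'
#' Runs the forward pass in train mode, evaluates the class-weighted
#' cross-entropy, and backpropagates through the full stack.
#'
#' @param params network parameters.
#' @param arch the matching architecture.
#' @param images list of zero-centered image matrices (the minibatch).
#' @param truth list of label matrices.
#' @param weights 4-vector of class weights.
#' @return list with `loss`, `grads` (flat named list congruent with the
#'   trainable parameters), `params` (updated batch-norm running statistics),
#'   and `accuracy` (global pixel accuracy of the batch predictions).
#' @export
loss_gradients <- function(params, arch, images, truth, weights) {
  x <- as_tensor(images)
  fwd <- segnet_forward(params, arch, x, mode = "train", keep_cache = TRUE)
  loss <- weighted_cross_entropy(fwd$probs, truth, weights)
  dscores <- wce_score_gradient(fwd$probs, truth, weights)
  grads <- segnet_backward(fwd$params, arch, fwd$cache, dscores)
  pred <- predict_labels(fwd$probs)
  if (is.matrix(truth)) truth <- list(truth)
  acc <- mean(mapply(function(p, t) mean(p == t), pred, truth))
  list(loss = loss, grads = grads, params = fwd$params, accuracy = acc)
}

#' Randomly augment an image/label pair
#'
#' With probability 1/2 the pair is mirrored across the X axis, then rotated
#' about the image center by an angle drawn uniformly from
#' `[-rotation_range, +rotation_range]` degrees. The image is resampled
#' bilinearly, labels by nearest neighbor (so values stay in `{0,1,2,3}`);
#' out-of-canvas regions are filled with background. Shapes are preserved.
#'
#' @param image numeric matrix.
#' @param labels integer label matrix of identical shape.
#' @param rotation_range half-width of the rotation range, degrees.
#' @param reflect allow the random mirroring.
#' @return list with augmented `image` and `labels`.
#' @export
augment_pair <- function(image, labels, rotation_range = 10, reflect = TRUE) {
  stopifnot(identical(dim(image), dim(labels)))
  if (reflect && stats::runif(1) < 0.5) {
    image <- image[, rev(seq_len(ncol(image))), drop = FALSE]
    labels <- labels[, rev(seq_len(ncol(labels))), drop = FALSE]
  }
  angle <- stats::runif(1, -rotation_range, rotation_range)
  if (angle != 0) {
    image <- rotate_matrix(image, angle, interp = "bilinear", fill = 0)
    labels <- rotate_matrix(labels, angle, interp = "nearest", fill = 0L)
  }
  list(image = image, labels = labels)
}

# Rotate a matrix about its center by `angle` degrees (counter-clockwise in
# the row/column plane) using inverse mapping. interp: bilinear | nearest.
rotate_matrix <- function(x, angle, interp = c("bilinear", "nearest"), fill = 0) {
  interp <- match.arg(interp)
  H <- nrow(x); W <- ncol(x)
  th <- angle * pi / 180
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  hh <- matrix(seq_len(H), H, W) - cy
  ww <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  # inverse rotation of output coordinates into the source image
  sh <- cos(th) * hh + sin(th) * ww + cy
  sw <- -sin(th) * hh + cos(th) * ww + cx
  if (interp == "nearest") {
    ih <- round(sh); iw <- round(sw)
    ok <- ih >= 1 & ih <= H & iw >= 1 & iw <= W
    out <- matrix(fill, H, W)
    out[ok] <- x[cbind(ih[ok], iw[ok])]
    storage.mode(out) <- storage.mode(x)
    return(out)
  }
  h0 <- floor(sh); w0 <- floor(sw)
  fh <- sh - h0; fw <- sw - w0
  gv <- function(ih, iw) {
    ok <- ih >= 1 & ih <= H & iw >= 1 & iw <= W
    v <- matrix(fill, H, W)
    v[ok] <- x[cbind(ih[ok], iw[ok])]
    v
  }
  out <- gv(h0, w0) * (1 - fh) * (1 - fw) + gv(h0 + 1, w0) * fh * (1 - fw) +
    gv(h0, w0 + 1) * (1 - fh) * fw + gv(h0 + 1, w0 + 1) * fh * fw
  out
}

#' One step of stochastic gradient descent with momentum
#'
#' `v <- momentum * v - lr * g; theta <- theta + v` for every trainable
#' array.
#'
#' @param params network parameters.
#' @param grads flat named gradient list from [loss_gradients()].
#' @param state optimizer state (`NULL` starts from zero velocity).
#' @param lr learning rate.
#' @param momentum momentum coefficient in `[0, 1)`.
#' @return list with updated `params` and `state`.
#' @export
sgdm_step <- function(params, grads, state = NULL, lr = 0.001, momentum = 0.9) {
  flat <- trainable_list(params)
  if (is.null(state)) state <- lapply(flat, function(a) array(0, dim(a) %||% length(a)))
  for (nm in names(grads)) {
    state[[nm]] <- momentum * state[[nm]] - lr * as.numeric(grads[[nm]])
    flat[[nm]] <- flat[[nm]] + array(state[[nm]], dim(flat[[nm]]) %||% length(flat[[nm]]))
  }
  list(params = set_trainable(params, flat), state = state)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Configure a training run
#'
#' @param learning_rate initial (and only) learning rate.
#' @param momentum SGDM momentum coefficient.
#' @param batch_size minibatch size.
#' @param max_epochs upper bound on epochs.
#' @param seed seed covering initialization, shuffling and augmentation.
#' @param augment apply random reflection/rotation on the fly each epoch.
#' @param rotation_range augmentation rotation half-range, degrees.
#' @param class_weights `"median-frequency"` or `"uniform"`.
#' @param filter_width hidden-layer filter count (64 = reference network).
#' @param patience stop early after this many consecutive epochs with
#'   training-loss improvement below `min_delta`.
#' @param min_delta improvement threshold for the early-stop rule.
#' @param verbose print one line per epoch.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, momentum = 0.9, batch_size = 8L,
                         max_epochs = 40L, seed = 1L, augment = TRUE,
                         rotation_range = 10, class_weights = "median-frequency",
                         filter_width = 64L, patience = 10L, min_delta = 1e-4,
                         verbose = FALSE) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1, batch_size >= 1)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), seed = as.integer(seed),
                 augment = isTRUE(augment), rotation_range = rotation_range,
                 class_weights = class_weights,
                 filter_width = as.integer(filter_width),
                 patience = as.integer(patience), min_delta = min_delta,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

# Core epoch loop. pairs: list with $image and $labels per item (images raw;
# zero-centering is applied here so training and prediction agree).
train_network <- function(pairs, cfg) {
  stopifnot(length(pairs) >= 1L)
  images <- lapply(pairs, function(p) zero_center(p$image))
  labels <- lapply(pairs, function(p) p$labels)
  weights <- compute_class_weights(labels, cfg$class_weights)
  arch <- build_architecture(cfg$filter_width)
  params <- init_params(arch, seed = cfg$seed)
  set.seed(cfg$seed + 1L)
  state <- NULL
  n <- length(images)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        accuracy = numeric(), seconds = numeric())
  best <- list(loss = Inf, params = params)
  stall <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    t0 <- proc.time()[["elapsed"]]
    ord <- sample.int(n)
    losses <- c(); accs <- c()
    for (start in seq(1L, n, by = cfg$batch_size)) {
      take <- ord[seq.int(start, min(start + cfg$batch_size - 1L, n))]
      bi <- images[take]; bl <- labels[take]
      if (cfg$augment) {
        for (j in seq_along(take)) {
          a <- augment_pair(bi[[j]], bl[[j]], cfg$rotation_range)
          bi[[j]] <- a$image; bl[[j]] <- a$labels
        }
      }
      lg <- loss_gradients(params, arch, bi, bl, weights)
      params <- lg$params
      upd <- sgdm_step(params, lg$grads, state, cfg$learning_rate, cfg$momentum)
      params <- upd$params; state <- upd$state
      losses <- c(losses, lg$loss); accs <- c(accs, lg$accuracy)
    }
    el <- proc.time()[["elapsed"]] - t0
    epoch_loss <- mean(losses)
    history <- rbind(history, data.frame(epoch = epoch, loss = epoch_loss,
                                         accuracy = mean(accs), seconds = el))
    if (cfg$verbose)
      message(sprintf("epoch %3d  loss %.5f  acc %.4f  lr %g  (%.1fs)",
                      epoch, epoch_loss, mean(accs), cfg$learning_rate, el))
    if (epoch_loss < best$loss - cfg$min_delta) {
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    if (epoch_loss < best$loss) best <- list(loss = epoch_loss, params = params)
    if (stall >= cfg$patience) break
  }
  list(params = best$params, final_params = params, history = history,
       class_weights = weights, arch = arch, config = cfg)
}
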