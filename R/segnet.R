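# The user-facing model: segnet() fits the network on image/label pairs and
# returns a classed object with the usual accessor methods.

#' Fit the compact SegNet to image/label pairs
#'
#' Trains the two-encoder/two-decoder network end to end with class-weighted
#' cross-entropy and stochastic gradient descent with momentum. Inputs are
#' zero-centered internally; spatial dimensions must be divisible by 4.
#' Training is deterministic given `seed` (single-threaded contract):
#' initialization, epoch shuffling and augmentation all draw from one seeded
#' stream.
#'
#' @param x the training data: a list of `phantom_pair`s (or any list whose
#'   elements have `$image` and `$labels`), or a list of image matrices with
#'   labels supplied in `y`.
#' @param y list of integer label matrices when `x` holds bare images.
#' @param filter_width hidden filter count; 64 is the reference network
#'   (225,420 trainable parameters), smaller values give fast reduced nets.
#' @param epochs maximum number of epochs; training stops early once the
#'   epoch loss has improved by less than `min_delta` for `patience`
#'   consecutive epochs.
#' @param learning_rate,momentum,batch_size optimizer settings (defaults
#'   0.001, 0.9, 8).
#' @param seed integer seed for the whole run.
#' @param augment random X-axis reflection and rotation within
#'   `rotation_range` degrees, applied on the fly each epoch.
#' @param rotation_range augmentation rotation half-range in degrees.
#' @param class_weights `"median-frequency"` (default) or `"uniform"`.
#' @param patience,min_delta early-stopping rule (see `epochs`).
#' @param verbose print one line per epoch.
#' @return an object of class `"segnet"`: the trained parameters (best epoch
#'   by training loss), architecture, per-epoch history, class weights and
#'   configuration.
#' @seealso [predict.segnet()], [evaluate_segmentation()], [save_segnet()]
#' @examples
#' d <- generate_dataset(4, phantom_spec(height = 32, width = 32), seed = 7)
#' fit <- segnet(d$train, filter_width = 4, epochs = 2, batch_size = 2,
#'               seed = 7)
#' pred <- predict(fit, d$test[[1]]$image)
#' @export
segnet <- function(x, y = NULL, filter_width = 64L, epochs = 40L,
                   learning_rate = 0.001, momentum = 0.9, batch_size = 8L,
                   seed = 1L, augment = TRUE, rotation_range = 10,
                   class_weights = "median-frequency", patience = 10L,
                   min_delta = 1e-4, verbose = FALSE) {
  pairs <- normalize_pairs(x, y)
  cfg <- train_config(learning_rate = learning_rate, momentum = momentum,
                      batch_size = batch_size, max_epochs = epochs,
                      seed = seed, augment = augment,
                      rotation_range = rotation_range,
                      class_weights = class_weights,
                      filter_width = filter_width, patience = patience,
                      min_delta = min_delta, verbose = verbose)
  fit <- train_network(pairs, cfg)
  structure(list(params = fit$params, arch = fit$arch, history = fit$history,
                 class_weights = fit$class_weights, config = cfg,
                 call = match.call()),
            class = "segnet")
}

normalize_pairs <- function(x, y = NULL) {
  if (!is.null(y)) {
    stopifnot(is.list(x), is.list(y), length(x) == length(y))
    return(mapply(function(i, l) list(image = i, labels = l),
                  x, y, SIMPLIFY = FALSE))
  }
  stopifnot(is.list(x), length(x) >= 1L)
  lapply(x, function(p) {
    if (is.null(p$image) || is.null(p$labels))
      stop("each training item needs $image and $labels")
    list(image = p$image, labels = p$labels)
  })
}

#' @export
print.segnet <- function(x, ...) {
  h <- x$history
  cat(sprintf("compact SegNet fit: filter width %d, %s trainable parameters\n",
              x$arch$filter_width,
              format(count_trainable(x$params), big.mark = ",")))
  cat(sprintf("trained %d epoch(s); best training loss %.5f, final accuracy %.4f\n",
              nrow(h), min(h$loss), h$accuracy[nrow(h)]))
  invisible(x)
}

#' @export
summary.segnet <- function(object, ...) {
  structure(list(
    filter_width = object$arch$filter_width,
    n_layers = length(object$arch$layers),
    n_parameters = count_trainable(object$params),
    epochs = nrow(object$history),
    best_loss = min(object$history$loss),
    final_accuracy = object$history$accuracy[nrow(object$history)],
    class_weights = object$class_weights,
    config = object$config,
    history = object$history
  ), class = "summary.segnet")
}

#' @export
print.summary.segnet <- function(x, ...) {
  cat(sprintf("compact SegNet (%d layers, filter width %d, %s parameters)\n",
              x$n_layers, x$filter_width,
              format(x$n_parameters, big.mark = ",")))
  cat(sprintf("epochs: %d  best loss: %.5f  final training accuracy: %.4f\n",
              x$epochs, x$best_loss, x$final_accuracy))
  cat("class weights:\n")
  print(round(x$class_weights, 4))
  cat(sprintf("optimizer: SGDM lr %g momentum %g, batch size %d, seed %d\n",
              x$config$learning_rate, x$config$momentum, x$config$batch_size,
              x$config$seed))
  invisible(x)
}

#' @export
coef.segnet <- function(object, ...) trainable_list(object$params)

#' Segment new slices with a trained network
#'
#' Applies the training-time preparation (zero-centering, padding to a
#' multiple of 4 with exact un-padding) and runs the network in inference
#' mode (batch norm uses running statistics).
#'
#' @param object a fitted [segnet()] model.
#' @param newdata an image matrix, a list of image matrices, or a
#'   `phantom_pair` (whose `$image` is used).
#' @param type `"class"` for integer label maps, `"prob"` for the 4-channel
#'   probability tensor (one per input).
#' @param batch_size inference minibatch size.
#' @param ... unused.
#' @return a label matrix / list of label matrices, or probability arrays
#'   `(4, height, width)` for `type = "prob"`.
#' @export
predict.segnet <- function(object, newdata, type = c("class", "prob"),
                           batch_size = 8L, ...) {
  type <- match.arg(type)
  single <- FALSE
  if (is.matrix(newdata)) { newdata <- list(newdata); single <- TRUE }
  if (!is.null(newdata$image) && is.matrix(newdata$image)) {
    newdata <- list(newdata$image); single <- TRUE
  }
  imgs <- lapply(newdata, function(im) if (is.matrix(im)) im else im$image)
  out <- vector("list", length(imgs))
  for (start in seq(1L, length(imgs), by = batch_size)) {
    take <- seq.int(start, min(start + batch_size - 1L, length(imgs)))
    prep <- lapply(imgs[take], function(im) pad_to_multiple(zero_center(im)))
    x <- as_tensor(lapply(prep, `[[`, "image"))
    fwd <- segnet_forward(object$params, object$arch, x, mode = "infer")
    if (type == "class") {
      labs <- predict_labels(fwd$probs)
      out[take] <- mapply(function(l, p) crop_restore(l, p$crop),
                          labs, prep, SIMPLIFY = FALSE)
    } else {
      for (j in seq_along(take)) {
        pr <- fwd$probs[j, , , , drop = FALSE]
        cr <- prep[[j]]$crop
        pl <- lapply(1:4, function(c) crop_restore(
          matrix(pr[1, c, , ], dim(pr)[3L], dim(pr)[4L]), cr))
        out[[take[j]]] <- array(unlist(pl),
                                c(dim(pl[[1L]]), 4L))
        out[[take[j]]] <- aperm(out[[take[j]]], c(3L, 1L, 2L))
      }
    }
  }
  if (single) out[[1L]] else out
}

#' Plot training history
#'
#' Loss (left axis) and global training pixel accuracy (right axis) per
#' epoch.
#'
#' @param x a fitted [segnet()] model.
#' @param ... passed to [graphics::plot()].
#' @export
plot.segnet <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mar = c(4, 4, 2, 4))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "b", pch = 19, col = "firebrick",
                 xlab = "epoch", ylab = "training loss",
                 main = "compact SegNet training", ...)
  graphics::par(new = TRUE)
  graphics::plot(h$epoch, h$accuracy, type = "b", pch = 1, col = "steelblue",
                 axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  graphics::axis(4)
  graphics::mtext("training accuracy", side = 4, line = 2.5)
  invisible(x)
}
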