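# Segmentation evaluation: Dice / Jaccard on binary masks, gray-level
# rendering and intensity MSE, confusion-matrix statistics (global/mean
# accuracy, per-class and mean/weighted IoU), boundary-F1, and the combined
# per-image report.

check_masks <- function(x, y) {
  if (!identical(dim(x), dim(y))) stop("masks must have identical shapes")
  list(x = as.logical(x), y = as.logical(y))
}

#' Dice similarity coefficient
#'
#' `2 |x intersect y| / (|x| + |y|)`; defined as 1 when both masks are empty
#' (nothing to find, nothing found).
#'
#' @param x,y logical masks of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
dice <- function(x, y) {
  m <- check_masks(x, y)
  s <- sum(m$x) + sum(m$y)
  if (s == 0) return(1)
  2 * sum(m$x & m$y) / s
}

#' Jaccard similarity coefficient (intersection over union)
#'
#' `|x intersect y| / |x union y|`; 1 when both masks are empty. Related to
#' Dice by `J = D / (2 - D)`.
#'
#' @param x,y logical masks of identical shape.
#' @return scalar in `[0, 1]`.
#' @export
jaccard <- function(x, y) {
  m <- check_masks(x, y)
  u <- sum(m$x | m$y)
  if (u == 0) return(1)
  sum(m$x & m$y) / u
}

#' Render a label map at equally spaced gray levels
#'
#' Class `c` maps to `round(255 * c / 3)`, i.e. background/CSF/GM/WM become
#' 0/85/170/255 on the 8-bit scale.
#'
#' @param labels integer matrix over `{0,1,2,3}`.
#' @param levels the four gray levels, overridable.
#' @return numeric matrix of gray intensities.
#' @export
label_to_gray <- function(labels, levels = round(255 * 0:3 / 3)) {
  v <- as.integer(labels)
  if (any(!v %in% 0:3))
    stop("label map contains values outside {0,1,2,3}")
  matrix(levels[v + 1L], nrow(labels), ncol(labels))
}

#' Invert [label_to_gray()]
#'
#' @param gray matrix of gray intensities produced by [label_to_gray()].
#' @param levels the gray levels used for rendering.
#' @return integer label matrix.
#' @export
gray_to_label <- function(gray, levels = round(255 * 0:3 / 3)) {
  idx <- match(as.numeric(gray), levels)
  if (anyNA(idx)) stop("gray image contains levels outside the rendering map")
  matrix(idx - 1L, nrow(gray), ncol(gray))
}

#' Mean squared error between two gray images
#'
#' `(1 / (M * N)) * sum (I - I')^2` over all pixels.
#'
#' @param x,y numeric matrices of identical `M x N` shape (0-255 scale).
#' @return nonnegative scalar.
#' @export
mse_image <- function(x, y) {
  if (!identical(dim(x), dim(y))) stop("images must have identical shapes")
  mean((as.numeric(x) - as.numeric(y))^2)
}

#' 4-class confusion matrix
#'
#' @param pred,truth integer label matrices of identical shape with values in
#'   `{0,1,2,3}`.
#' @return 4x4 integer matrix of pixel counts; rows index the true class,
#'   columns the predicted class.
#' @export
confusion_matrix4 <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stop("label maps must have identical shapes")
  p <- as.integer(pred); t <- as.integer(truth)
  if (any(!p %in% 0:3) || any(!t %in% 0:3))
    stop("label maps contain values outside {0,1,2,3}")
  cm <- matrix(tabulate(t * 4L + p + 1L, nbins = 16L), 4L, 4L, byrow = TRUE)
  dimnames(cm) <- list(truth = c("background", "CSF", "GM", "WM"),
                       prediction = c("background", "CSF", "GM", "WM"))
  cm
}

#' Accuracy and IoU statistics from a confusion matrix
#'
#' Global accuracy is `trace / total`; per-class accuracy is the diagonal
#' over the row sum (recall); per-class IoU is
#' `diag / (rowsum + colsum - diag)`; means average the classes present in
#' the truth; weighted IoU weights each class IoU by its truth frequency.
#'
#' @param cm a [confusion_matrix4()] (counts, rows = truth).
#' @param frequencies optional class frequencies for the weighted IoU;
#'   defaults to the row sums of `cm` normalized to 1.
#' @return list with `global_accuracy`, `class_accuracy`, `mean_accuracy`,
#'   `class_iou`, `mean_iou`, `weighted_iou`.
#' @export
cm_statistics <- function(cm, frequencies = NULL) {
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix")
  rs <- rowSums(cm); cs <- colSums(cm); dg <- diag(cm)
  present <- rs > 0
  class_acc <- ifelse(present, dg / rs, NA_real_)
  denom <- rs + cs - dg
  class_iou <- ifelse(denom > 0, dg / denom, NA_real_)
  if (is.null(frequencies)) frequencies <- rs / total
  list(global_accuracy = sum(dg) / total,
       class_accuracy = class_acc,
       mean_accuracy = mean(class_acc[present]),
       class_iou = class_iou,
       mean_iou = mean(class_iou[present]),
       weighted_iou = sum(frequencies[present] * class_iou[present]))
}

# boundary pixels: mask pixels with at least one 4-neighbor outside the mask
# (the image border counts as outside)
boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(FALSE, H + 2L, W + 2L)
  pad[2:(H + 1L), 2:(W + 1L)] <- mask
  inner <- pad[1:H, 2:(W + 1L)] & pad[3:(H + 2L), 2:(W + 1L)] &
    pad[2:(H + 1L), 1:W] & pad[2:(H + 1L), 3:(W + 2L)]
  which(mask & !inner, arr.ind = TRUE)
}

#' Boundary-F1 (BF) score
#'
#' Precision is the fraction of predicted-boundary pixels lying within
#' `tolerance` (Euclidean pixels) of some true-boundary pixel; recall is the
#' symmetric quantity; the score is their harmonic mean. Two empty
#' boundaries score 1; exactly one empty boundary scores 0.
#'
#' @param pred,truth logical masks of identical shape.
#' @param tolerance match distance in pixels; the default is 0.75% of the
#'   image diagonal, rounded up and floored at 1 pixel.
#' @return scalar in `[0, 1]`.
#' @export
bf_score <- function(pred, truth, tolerance = NULL) {
  m <- check_masks(pred, truth)
  dim(m$x) <- dim(pred); dim(m$y) <- dim(truth)
  if (is.null(tolerance))
    tolerance <- max(1, ceiling(0.0075 * sqrt(sum(dim(pred)^2))))
  bp <- boundary_pixels(m$x)
  bt <- boundary_pixels(m$y)
  if (nrow(bp) == 0 && nrow(bt) == 0) return(1)
  if (nrow(bp) == 0 || nrow(bt) == 0) return(0)
  match_frac <- function(a, b) {
    # fraction of rows of a within tolerance of some row of b
    d2 <- outer(a[, 1L], b[, 1L], "-")^2 + outer(a[, 2L], b[, 2L], "-")^2
    mean(sqrt(apply(d2, 1L, min)) <= tolerance)
  }
  P <- match_frac(bp, bt)
  R <- match_frac(bt, bp)
  if (P + R == 0) return(0)
  2 * P * R / (P + R)
}

#' Full evaluation of a predicted label map against its ground truth
#'
#' Computes, per class, one-vs-rest Dice, Jaccard, IoU, accuracy and BF
#' score; globally, the confusion matrix, global/mean accuracy, mean and
#' weighted IoU, and the intensity MSE between the gray-rendered maps
#' ([label_to_gray()]). Mean Dice/Jaccard are reported over the three tissue
#' classes (CSF, GM, WM), excluding background.
#'
#' @param pred,truth integer label matrices over `{0,1,2,3}`.
#' @param bf_tolerance boundary-match tolerance passed to [bf_score()].
#' @param gray_levels gray rendering levels for the MSE.
#' @return a `segmentation_report` object.
#' @export
evaluate_segmentation <- function(pred, truth, bf_tolerance = NULL,
                                  gray_levels = round(255 * 0:3 / 3)) {
  if (!identical(dim(pred), dim(truth))) stop("label maps must have identical shapes")
  classes <- c("background", "CSF", "GM", "WM")
  per <- sapply(0:3, function(k) {
    px <- pred == k; tx <- truth == k
    c(dice = dice(px, tx), jaccard = jaccard(px, tx),
      bf = bf_score(px, tx, bf_tolerance))
  })
  colnames(per) <- classes
  cm <- confusion_matrix4(pred, truth)
  st <- cm_statistics(cm)
  tissue <- classes[-1L]
  structure(list(
    per_class = data.frame(
      class = classes,
      dice = per["dice", ], jaccard = per["jaccard", ],
      iou = as.numeric(st$class_iou), accuracy = as.numeric(st$class_accuracy),
      bf_score = per["bf", ], row.names = NULL),
    confusion_matrix = cm,
    global_accuracy = st$global_accuracy,
    mean_accuracy = st$mean_accuracy,
    mean_iou = st$mean_iou,
    weighted_iou = st$weighted_iou,
    mean_dice_tissue = mean(per["dice", tissue]),
    mean_jaccard_tissue = mean(per["jaccard", tissue]),
    mse = mse_image(label_to_gray(pred, gray_levels),
                    label_to_gray(truth, gray_levels))
  ), class = "segmentation_report")
}

#' @export
print.segmentation_report <- function(x, digits = 4, ...) {
  cat("Segmentation report\n")
  pc <- x$per_class
  pc[-1L] <- lapply(pc[-1L], round, digits)
  print(pc, row.names = FALSE)
  cat(sprintf("global accuracy %.4f | mean accuracy %.4f | mean IoU %.4f | weighted IoU %.4f\n",
              x$global_accuracy, x$mean_accuracy, x$mean_iou, x$weighted_iou))
  cat(sprintf("mean tissue Dice %.4f | mean tissue Jaccard %.4f | gray MSE %.2f\n",
              x$mean_dice_tissue, x$mean_jaccard_tissue, x$mse))
  invisible(x)
}

#' Serialize a segmentation report to JSON
#'
#' @param report a [evaluate_segmentation()] object (or a named list of
#'   them plus aggregate fields).
#' @param path optional destination file.
#' @return the JSON string, invisibly when written to `path`.
#' @export
report_to_json <- function(report, path = NULL) {
  to_plain <- function(r) {
    if (inherits(r, "segmentation_report")) {
      r <- unclass(r)
      r$confusion_matrix <- unname(apply(r$confusion_matrix, 1L, as.list,
                                         simplify = FALSE))
    }
    r
  }
  obj <- if (inherits(report, "segmentation_report")) to_plain(report)
         else lapply(report, to_plain)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
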