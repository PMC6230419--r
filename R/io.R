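# Reading/writing the formats the pipeline touches: Analyze 7.5 and NIfTI-1
# volumes (via oro.nifti / RNifti), 8-bit PNG label maps with raw class
# indices, and slice preparation (zero-centering, padding to a multiple of 4).
# Volumes are kept in the on-disk axis order reported by the format library;
# the slicing axis is always explicit.

#' Read a 3D volume from Analyze 7.5 or NIfTI
#'
#' Analyze pairs (`.hdr`/`.img`, optionally gzipped) are read with
#' \pkg{oro.nifti}; `.nii`/`.nii.gz` with \pkg{RNifti}. The array keeps the
#' on-disk axis order of the format library.
#'
#' @param path path to a `.nii`, `.nii.gz`, `.hdr` or `.img` file (for
#'   Analyze, either member of the pair, or the common stem).
#' @return a `volume` object: list with `data` (3D array), `source_format`
#'   and `path`.
#' @export
read_volume <- function(path) {
  lower <- tolower(path)
  is_nifti <- grepl("\\.nii(\\.gz)?$", lower)
  if (is_nifti) {
    if (!file.exists(path)) stop("no such file: ", path)
    arr <- as.array(RNifti::readNifti(path))
    fmt <- "NIfTI"
  } else {
    stem <- sub("\\.(hdr|img)(\\.gz)?$", "", path)
    has <- function(ext) file.exists(paste0(stem, ext)) || file.exists(paste0(stem, ext, ".gz"))
    if (!has(".hdr") || !has(".img"))
      stop("Analyze pair incomplete: need both ", stem, ".hdr and ", stem,
           ".img (optionally gzipped)")
    arr <- oro.nifti::readANALYZE(stem)@.Data
    fmt <- "Analyze"
  }
  arr <- drop(arr)
  if (length(dim(arr)) != 3L)
    stop(sprintf("expected a 3D volume, payload has %d dimensions after dropping singletons",
                 length(dim(arr))))
  if (!all(is.finite(arr))) stop("volume contains non-finite values")
  structure(list(data = arr, source_format = fmt, path = path),
            class = "volume")
}

#' Write a 3D volume (helper for tests and round trips)
#'
#' @param data 3D numeric array.
#' @param path destination: `.nii`/`.nii.gz`, or an Analyze stem/`.hdr` path
#'   (written as a gzipped `.hdr.gz`/`.img.gz` pair).
#' @return `path`, invisibly.
#' @export
write_volume <- function(data, path) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (grepl("\\.nii(\\.gz)?$", tolower(path))) {
    RNifti::writeNifti(RNifti::asNifti(data), path)
  } else {
    stem <- sub("\\.(hdr|img)(\\.gz)?$", "", path)
    oro.nifti::writeANALYZE(oro.nifti::as.anlz(data), stem)
  }
  invisible(path)
}

#' Extract a 2D slice from a volume
#'
#' @param vol a [read_volume()] object (or bare 3D array).
#' @param axis axis to slice across: 1, 2 or 3 in the volume's stored order.
#' @param index 1-based plane index; defaults to the mid-plane.
#' @return a numeric matrix (the remaining two axes, in order).
#' @export
extract_slice <- function(vol, axis = 3L, index = NULL) {
  arr <- if (inherits(vol, "volume")) vol$data else vol
  stopifnot(length(dim(arr)) == 3L)
  axis <- as.integer(axis)
  if (!axis %in% 1:3) stop("axis must be 1, 2 or 3")
  n <- dim(arr)[axis]
  if (is.null(index)) index <- (n + 1L) %/% 2L
  if (index < 1L || index > n)
    stop(sprintf("slice index %d out of range 1..%d on axis %d", index, n, axis))
  switch(axis,
         matrix(arr[index, , ], dim(arr)[2L], dim(arr)[3L]),
         matrix(arr[, index, ], dim(arr)[1L], dim(arr)[3L]),
         matrix(arr[, , index], dim(arr)[1L], dim(arr)[2L]))
}

#' Zero-center an image slice
#'
#' @param image numeric matrix.
#' @return `image - mean(image)`.
#' @export
zero_center <- function(image) {
  stopifnot(is.matrix(image), length(image) > 0L)
  image - mean(image)
}

#' Pad a slice (and optional labels) to the next multiple of a factor
#'
#' Symmetric padding: images are padded with 0 (the background fill of a
#' zero-centered, skull-stripped slice), labels with the background class.
#' The returned crop record inverts the padding exactly via [crop_restore()].
#'
#' @param image numeric matrix.
#' @param labels optional integer label matrix of identical shape.
#' @param factor divisibility target (4 for the two 2x poolings).
#' @return list with `image`, `labels` (or `NULL`) and `crop`
#'   (`list(top, left, height, width)`; `NULL` when nothing was padded).
#' @export
pad_to_multiple <- function(image, labels = NULL, factor = 4L) {
  d <- dim(image)
  target <- ceiling(d / factor) * factor
  if (all(target == d))
    return(list(image = image, labels = labels, crop = NULL))
  pad <- target - d
  top <- pad[1L] %/% 2L; left <- pad[2L] %/% 2L
  place <- function(x, fill) {
    out <- matrix(fill, target[1L], target[2L])
    out[top + seq_len(d[1L]), left + seq_len(d[2L])] <- x
    out
  }
  list(image = place(image, 0),
       labels = if (!is.null(labels)) place(labels, 0L),
       crop = list(top = top, left = left, height = d[1L], width = d[2L]))
}

#' Invert [pad_to_multiple()]
#'
#' @param x padded matrix.
#' @param crop the crop record returned by [pad_to_multiple()] (`NULL` means
#'   no padding happened).
#' @return the original-extent matrix.
#' @export
crop_restore <- function(x, crop) {
  if (is.null(crop)) return(x)
  x[crop$top + seq_len(crop$height), crop$left + seq_len(crop$width), drop = FALSE]
}

#' Write a label map as an 8-bit grayscale PNG with raw class indices
#'
#' @param labels integer matrix with values in `{0, 1, 2, 3}`.
#' @param path destination `.png`.
#' @return `path`, invisibly.
#' @export
write_label_png <- function(labels, path) {
  stopifnot(is.matrix(labels))
  vals <- unique(as.integer(labels))
  bad <- setdiff(vals, 0:3)
  if (length(bad))
    stop("label map contains values outside {0,1,2,3}: ", paste(bad, collapse = ", "))
  png::writePNG(labels / 255, path)
  invisible(path)
}

#' Read a label map written by [write_label_png()]
#'
#' @param path a single-channel 8-bit PNG holding raw class indices.
#' @return integer label matrix.
#' @export
read_label_png <- function(path) {
  raw <- png::readPNG(path)
  if (length(dim(raw)) == 3L) {
    if (dim(raw)[3L] > 1L) stop("label PNG must be single-channel")
    raw <- raw[, , 1L]
  }
  lab <- as.integer(round(raw * 255))
  bad <- setdiff(unique(lab), 0:3)
  if (length(bad))
    stop("label PNG contains values outside {0,1,2,3}: ", paste(bad, collapse = ", "))
  matrix(lab, nrow(raw), ncol(raw))
}

#' Write a 2D float image slice as NIfTI
#'
#' @param image numeric matrix.
#' @param path destination `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_image_nifti <- function(image, path) {
  stopifnot(is.matrix(image))
  RNifti::writeNifti(RNifti::asNifti(array(image, c(dim(image), 1L))), path,
                     datatype = "double")
  invisible(path)
}

#' Read a 2D image slice written by [write_image_nifti()]
#'
#' @param path a `.nii`/`.nii.gz` file holding one slice.
#' @return numeric matrix.
#' @export
read_image_nifti <- function(path) {
  arr <- drop(as.array(RNifti::readNifti(path)))
  if (length(dim(arr)) != 2L) stop("expected a single 2D slice in ", path)
  matrix(as.numeric(arr), dim(arr)[1L], dim(arr)[2L])
}
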