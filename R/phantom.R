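# Synthetic skull-stripped T1-like brain phantoms with exact ground truth.
# Geometry is nested ellipses: an outer CSF band, a gray-matter band inside
# it, a white-matter core, and optional small CSF "ventricle" ellipses placed
# well inside the core. Intensity follows T1 contrast (CSF < GM < WM), a
# smooth multiplicative bias bump emulates scanner inhomogeneity, additive
# Gaussian noise is applied to brain pixels, and background stays exactly 0
# as in skull-stripped acquisitions.

#' Specification of a synthetic brain phantom
#'
#' @param height,width canvas size in pixels; each must be divisible by 4 so
#'   the network's two 2x poolings invert cleanly.
#' @param mean_intensity named vector of tissue mean intensities in `[0, 1]`,
#'   ordered CSF < GM < WM (T1 contrast); background is fixed at 0.
#' @param noise_sigma standard deviation of additive Gaussian noise applied to
#'   brain pixels (intensity units).
#' @param bias_amplitude relative amplitude of the smooth multiplicative bias
#'   field; the field spans `1 - a` to `1 + a`.
#' @param rim_fractions named vector: CSF and GM band thicknesses as fractions
#'   of the brain ellipse radius.
#' @param n_ventricles number of small CSF ellipses placed inside the WM core.
#' @param jitter relative randomization of ellipse centers, axes and
#'   orientation between phantoms.
#' @param seed integer seed; a phantom is a pure function of its spec.
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(height = 96L, width = 96L,
                         mean_intensity = c(CSF = 0.2, GM = 0.5, WM = 0.8),
                         noise_sigma = 0.05, bias_amplitude = 0.2,
                         rim_fractions = c(CSF = 0.15, GM = 0.30),
                         n_ventricles = 2L, jitter = 0.1, seed = 1L) {
  height <- as.integer(height); width <- as.integer(width)
  if (height %% 4L != 0L || width %% 4L != 0L)
    stop(sprintf("phantom dimensions must be divisible by 4, got %d x %d",
                 height, width))
  mi <- mean_intensity
  if (length(mi) != 3L || any(is.na(mi)) || any(mi <= 0) || any(mi > 1))
    stop("mean_intensity must give CSF, GM, WM values in (0, 1]")
  if (!(mi[["CSF"]] < mi[["GM"]] && mi[["GM"]] < mi[["WM"]]))
    stop("T1-like contrast requires mean intensities CSF < GM < WM")
  if (noise_sigma < 0 || bias_amplitude < 0)
    stop("noise_sigma and bias_amplitude must be nonnegative")
  rf <- rim_fractions
  if (any(rf <= 0) || sum(rf) >= 0.9)
    stop("rim fractions must be positive and leave room for a WM core")
  structure(list(height = height, width = width, mean_intensity = mi,
                 noise_sigma = noise_sigma, bias_amplitude = bias_amplitude,
                 rim_fractions = rf, n_ventricles = as.integer(n_ventricles),
                 jitter = jitter, seed = as.integer(seed)),
            class = "phantom_spec")
}

# squared normalized radius of pixel grid w.r.t. a rotated ellipse
ellipse_r2 <- function(hh, ww, cy, cx, a, b, theta) {
  dy <- hh - cy; dx <- ww - cx
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  (u / a)^2 + (v / b)^2
}

#' Generate one phantom image/label pair
#'
#' Deterministic given the spec (which includes the seed): the same spec
#' always yields a bit-identical pair.
#'
#' @param spec a [phantom_spec()].
#' @return a `phantom_pair`: list with `image` (height x width intensity
#'   matrix in `[0, 1]`), `labels` (integer matrix over 0=background, 1=CSF,
#'   2=GM, 3=WM), `geometry` (the realized ellipses) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  jit <- function(x, rel) x * (1 + stats::runif(1, -rel, rel))
  # brain ellipse: centered, semi-axes a (cols) >= b (rows) scaled to canvas
  cx <- jit(W / 2, spec$jitter / 2); cy <- jit(H / 2, spec$jitter / 2)
  a <- jit(0.42 * W, spec$jitter); b <- jit(0.40 * H, spec$jitter)
  theta <- stats::runif(1, -pi, pi) * spec$jitter
  hh <- matrix(seq_len(H), H, W)
  ww <- matrix(seq_len(W), H, W, byrow = TRUE)
  r <- sqrt(ellipse_r2(hh, ww, cy, cx, a, b, theta))
  f_csf <- spec$rim_fractions[["CSF"]]; f_gm <- spec$rim_fractions[["GM"]]
  labels <- matrix(0L, H, W)
  labels[r <= 1] <- 1L                        # CSF rim
  labels[r <= 1 - f_csf] <- 2L                # GM band
  core <- 1 - f_csf - f_gm
  labels[r <= core] <- 3L                     # WM core
  ventricles <- list()
  if (spec$n_ventricles > 0L) {
    for (k in seq_len(spec$n_ventricles)) {
      # place strictly inside the WM core at a bounded normalized radius
      ang <- stats::runif(1, 0, 2 * pi)
      rad <- stats::runif(1, 0.15, 0.45) * core
      vcx <- cx + rad * a * cos(ang)
      vcy <- cy + rad * b * sin(ang)
      va <- jit(0.10 * a * core, spec$jitter)
      vb <- jit(0.16 * b * core, spec$jitter)
      vth <- stats::runif(1, -pi / 4, pi / 4)
      inside <- ellipse_r2(hh, ww, vcy, vcx, va, vb, vth) <= 1
      labels[inside & labels == 3L] <- 1L
      ventricles[[k]] <- list(cy = vcy, cx = vcx, a = va, b = vb, theta = vth)
    }
  }
  means <- c(0, spec$mean_intensity[["CSF"]], spec$mean_intensity[["GM"]],
             spec$mean_intensity[["WM"]])
  img <- matrix(means[labels + 1L], H, W)
  # bias: one smooth Gaussian bump with random center, spanning 1 +/- amplitude
  bcx <- stats::runif(1, 0.2 * W, 0.8 * W)
  bcy <- stats::runif(1, 0.2 * H, 0.8 * H)
  sigma <- 0.5 * min(H, W)
  g <- exp(-((hh - bcy)^2 + (ww - bcx)^2) / (2 * sigma^2))
  bias <- 1 - spec$bias_amplitude + 2 * spec$bias_amplitude * g
  img <- img * bias
  if (spec$noise_sigma > 0) {
    noise <- matrix(stats::rnorm(H * W, 0, spec$noise_sigma), H, W)
    img[labels > 0L] <- img[labels > 0L] + noise[labels > 0L]
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  img[labels == 0L] <- 0
  structure(list(image = img, labels = labels,
                 geometry = list(brain = list(cy = cy, cx = cx, a = a, b = b,
                                              theta = theta),
                                 ventricles = ventricles,
                                 bias_center = c(bcy, bcx)),
                 spec = spec),
            class = "phantom_pair")
}

#' Generate a reproducible phantom dataset with a train/test split
#'
#' Per-item seeds are `seed + item index`, so any subset is reproducible and
#' two calls with the same master seed return identical datasets. The first
#' `round(n * split_fraction)` items form the training set.
#'
#' @param n number of phantoms (>= 2).
#' @param spec template [phantom_spec()]; each item reuses it with its own
#'   derived seed.
#' @param seed master seed.
#' @param split_fraction fraction of items assigned to the training set; both
#'   partitions must end up non-empty.
#' @param dir optional directory: when given, images are written as
#'   `img_<i>.nii.gz`, labels as `lab_<i>.png`, and a `dataset.json` sidecar
#'   records the spec and per-item geometry.
#' @return list with `train` and `test` lists of `phantom_pair`s.
#' @export
generate_dataset <- function(n, spec, seed = 1L, split_fraction = 0.8,
                             dir = NULL) {
  n <- as.integer(n)
  if (n < 2L) stop("a dataset needs at least 2 phantoms")
  n_train <- round(n * split_fraction)
  if (n_train < 1L || n_train >= n)
    stop("split_fraction would leave an empty train or test partition")
  pairs <- vector("list", n)
  for (i in seq_len(n)) {
    s <- spec
    s$seed <- as.integer(seed + i)
    pairs[[i]] <- generate_phantom(s)
    pairs[[i]]$id <- sprintf("phantom_%03d", i)
  }
  out <- list(train = pairs[seq_len(n_train)],
              test = pairs[seq.int(n_train + 1L, n)])
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    sidecar <- list(spec = unclass(spec), master_seed = seed,
                    split_fraction = split_fraction, items = list())
    for (p in pairs) {
      write_image_nifti(p$image, file.path(dir, paste0(p$id, ".nii.gz")))
      write_label_png(p$labels, file.path(dir, paste0(p$id, "_label.png")))
      sidecar$items[[p$id]] <- list(seed = p$spec$seed, geometry = p$geometry)
    }
    jsonlite::write_json(sidecar, file.path(dir, "dataset.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Class pixel frequencies of a set of label maps
#'
#' @param labels a label matrix or list of label matrices.
#' @return named numeric vector of the four class frequencies (sums to 1).
#' @export
class_frequencies <- function(labels) {
  if (is.matrix(labels)) labels <- list(labels)
  counts <- rep(0, 4)
  for (l in labels) counts <- counts + tabulate(as.integer(l) + 1L, nbins = 4L)
  stats::setNames(counts / sum(counts), c("background", "CSF", "GM", "WM"))
}
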