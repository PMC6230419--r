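# Brute-force reference implementations used as independent oracles. Each is
# a direct transcription of the operation's definition with explicit loops;
# none shares code with the package's optimized paths.

`%||%` <- function(a, b) if (is.null(a)) b else a

rand_tensor <- function(n, c, h, w, sd = 1) {
  array(stats::rnorm(n * c * h * w, sd = sd), c(n, c, h, w))
}

oracle_conv3x3 <- function(x, W, b) {
  d <- dim(x); kd <- dim(W)
  y <- array(0, c(d[1], kd[1], d[3], d[4]))
  for (n in seq_len(d[1])) for (co in seq_len(kd[1]))
    for (h in seq_len(d[3])) for (w in seq_len(d[4])) {
      acc <- b[co]
      for (ci in seq_len(d[2])) for (kh in 1:3) for (kw in 1:3) {
        hi <- h + kh - 2; wi <- w + kw - 2
        if (hi >= 1 && hi <= d[3] && wi >= 1 && wi <= d[4])
          acc <- acc + x[n, ci, hi, wi] * W[co, ci, kh, kw]
      }
      y[n, co, h, w] <- acc
    }
  y
}

oracle_maxpool <- function(x) {
  d <- dim(x)
  ho <- d[3] / 2; wo <- d[4] / 2
  y <- array(0, c(d[1], d[2], ho, wo))
  idx <- array(0L, c(d[1], d[2], ho, wo))
  for (n in seq_len(d[1])) for (c in seq_len(d[2]))
    for (h in seq_len(ho)) for (w in seq_len(wo)) {
      best <- -Inf; bp <- 0L
      for (dh in 0:1) for (dw in 0:1) {     # row-major scan fixes the tie rule
        hi <- 2 * h - 1 + dh; wi <- 2 * w - 1 + dw
        v <- x[n, c, hi, wi]
        if (v > best) { best <- v; bp <- hi + d[3] * (wi - 1) }
      }
      y[n, c, h, w] <- best; idx[n, c, h, w] <- bp
    }
  list(values = y, indices = idx)
}

oracle_unpool <- function(x, idx, out_dim) {
  d <- dim(x)
  y <- array(0, c(d[1], d[2], out_dim[1], out_dim[2]))
  for (n in seq_len(d[1])) for (c in seq_len(d[2]))
    for (h in seq_len(d[3])) for (w in seq_len(d[4])) {
      pos <- idx[n, c, h, w]
      hi <- (pos - 1) %% out_dim[1] + 1
      wi <- (pos - 1) %/% out_dim[1] + 1
      y[n, c, hi, wi] <- x[n, c, h, w]
    }
  y
}

oracle_bn_train <- function(x, gamma, beta, eps = 1e-5) {
  d <- dim(x)
  y <- array(0, d)
  for (c in seq_len(d[2])) {
    v <- as.numeric(x[, c, , ])
    mu <- mean(v)
    va <- mean((v - mu)^2)
    y[, c, , ] <- gamma[c] * (x[, c, , ] - mu) / sqrt(va + eps) + beta[c]
  }
  y
}

oracle_mse <- function(a, b) {
  s <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a)))
    s <- s + (a[i, j] - b[i, j])^2
  s / (nrow(a) * ncol(a))
}

oracle_confusion <- function(pred, truth) {
  cm <- matrix(0L, 4, 4)
  for (i in seq_len(nrow(pred))) for (j in seq_len(ncol(pred)))
    cm[truth[i, j] + 1, pred[i, j] + 1] <- cm[truth[i, j] + 1, pred[i, j] + 1] + 1L
  cm
}

oracle_argmax_labels <- function(probs) {
  d <- dim(probs)
  lapply(seq_len(d[1]), function(n) {
    out <- matrix(0L, d[3], d[4])
    for (h in seq_len(d[3])) for (w in seq_len(d[4])) {
      best <- -Inf; bk <- 0L
      for (k in seq_len(d[2])) if (probs[n, k, h, w] > best) {
        best <- probs[n, k, h, w]; bk <- k - 1L
      }
      out[h, w] <- bk
    }
    out
  })
}

# exhaustive boundary-F1: boundary = mask pixel with a 4-neighbor outside the
# mask or on the image border; precision/recall by all-pairs distances
oracle_bf <- function(pred, truth, tol) {
  bdry <- function(m) {
    pts <- NULL
    for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
      if (!m[i, j]) next
      nb <- c(if (i > 1) m[i - 1, j] else FALSE,
              if (i < nrow(m)) m[i + 1, j] else FALSE,
              if (j > 1) m[i, j - 1] else FALSE,
              if (j < ncol(m)) m[i, j + 1] else FALSE)
      if (!all(nb)) pts <- rbind(pts, c(i, j))
    }
    pts
  }
  bp <- bdry(pred); bt <- bdry(truth)
  if (is.null(bp) && is.null(bt)) return(1)
  if (is.null(bp) || is.null(bt)) return(0)
  near <- function(a, b) {
    hits <- 0
    for (i in seq_len(nrow(a))) {
      dmin <- Inf
      for (j in seq_len(nrow(b)))
        dmin <- min(dmin, sqrt(sum((a[i, ] - b[j, ])^2)))
      if (dmin <= tol) hits <- hits + 1
    }
    hits / nrow(a)
  }
  P <- near(bp, bt); R <- near(bt, bp)
  if (P + R == 0) return(0)
  2 * P * R / (P + R)
}

tiny_spec <- function(h = 16, w = 16, seed = 1, ...) {
  phantom_spec(height = h, width = w, n_ventricles = 1L, seed = seed, ...)
}
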