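test_that("convolution reproduces identity and window-sum special cases", {
  x <- rand_tensor(1, 1, 6, 6)
  delta <- array(0, c(1, 1, 3, 3)); delta[1, 1, 2, 2] <- 1
  expect_equal(conv2d_3x3_same(x, delta, 0), x, tolerance = 1e-14)

  ones <- array(1, c(1, 1, 3, 3))
  const <- array(2, c(1, 1, 5, 5))
  y <- conv2d_3x3_same(const, ones, 0)
  expect_equal(y[1, 1, 3, 3], 18)   # interior: 9 * 2
  expect_equal(y[1, 1, 1, 1], 8)    # corner: 4 * 2 (zero padding)
  expect_equal(y[1, 1, 1, 3], 12)   # edge: 6 * 2
})

test_that("convolution matches the nested-loop oracle", {
  set.seed(42)
  for (rep in 1:5) {
    x <- rand_tensor(2, 2, 5, 5)
    W <- array(stats::rnorm(3 * 2 * 9), c(3, 2, 3, 3))
    b <- stats::rnorm(3)
    expect_equal(conv2d_3x3_same(x, W, b), oracle_conv3x3(x, W, b),
                 tolerance = 1e-10)
  }
  expect_error(conv2d_3x3_same(rand_tensor(1, 2, 4, 4),
                               array(0, c(1, 3, 3, 3)), 0),
               "channel mismatch")
})

test_that("train-mode batch norm standardizes channels and matches its oracle", {
  set.seed(7)
  x <- rand_tensor(3, 4, 6, 6, sd = 3)
  bp <- bn_params(4)
  r <- batch_norm(x, bp, "train")
  for (c in 1:4) {
    v <- as.numeric(r$values[, c, , ])
    expect_lt(abs(mean(v)), 1e-10)
    expect_equal(mean(v^2), 1, tolerance = 1e-3)  # epsilon-regularized
  }
  expect_equal(r$values, oracle_bn_train(x, bp$gamma, bp$beta),
               tolerance = 1e-10)
  expect_equal(r$params$n_updates, 1L)

  xc <- x; xc[, 2, , ] <- 5  # constant channel collapses to beta
  bp2 <- bn_params(4); bp2$beta <- c(0, 0.7, 0, 0)
  r2 <- batch_norm(xc, bp2, "train")
  expect_equal(as.numeric(r2$values[, 2, , ]), rep(0.7, 3 * 36),
               tolerance = 1e-6)
})

test_that("inference-mode batch norm requires running statistics", {
  x <- rand_tensor(2, 3, 4, 4)
  expect_error(batch_norm(x, bn_params(3), "infer"), "running statistics")
  bp <- batch_norm(x, bn_params(3), "train")$params
  expect_silent(batch_norm(x, bp, "infer"))
})

test_that("relu clamps negatives and is idempotent", {
  expect_true(all(relu(rand_tensor(1, 1, 4, 4) - 100) == 0))
  xp <- abs(rand_tensor(1, 1, 4, 4))
  expect_identical(relu(xp), xp)
  x <- rand_tensor(2, 2, 4, 4)
  expect_identical(relu(relu(x)), relu(x))
})

test_that("max pooling memorizes argmax positions with a first-wins tie rule", {
  x <- array(0, c(1, 1, 2, 2)); x[1, 1, , ] <- matrix(c(1, 3, 2, 4), 2, 2)
  r <- maxpool2x2_with_indices(x)
  expect_equal(r$values[1, 1, 1, 1], 4)
  expect_equal(r$indices[1, 1, 1, 1], 4L)  # position of 4 in the 2x2 plane

  const <- array(5, c(1, 2, 4, 4))
  rc <- maxpool2x2_with_indices(const)
  expect_true(all(rc$values == 5))
  # ties keep the window's first (top-left) position
  expect_identical(as.integer(rc$indices[1, 1, , ]),
                   c(1L, 3L, 9L, 11L))
  expect_error(maxpool2x2_with_indices(rand_tensor(1, 1, 5, 4)), "even")
})

test_that("pooling and unpooling match their brute-force oracles", {
  set.seed(11)
  for (rep in 1:5) {
    x <- rand_tensor(2, 3, 8, 8)
    r <- maxpool2x2_with_indices(x)
    o <- oracle_maxpool(x)
    expect_equal(r$values, o$values)
    expect_identical(as.integer(r$indices), as.integer(o$indices))
    up <- maxunpool2x2(r$values, r$indices, c(8, 8))
    expect_equal(up, oracle_unpool(r$values, r$indices, c(8, 8)))
    # partial identity: maxima recovered in place, zeros elsewhere
    expect_true(all(up[up != 0] == x[up != 0]))
    expect_equal(sum(up != 0), 2 * 3 * 16)
  }
})

test_that("unpooling an all-distinct 4x4 input leaves one value per window", {
  x <- array(0, c(1, 1, 4, 4)); x[1, 1, , ] <- matrix(1:16, 4, 4)
  r <- maxpool2x2_with_indices(x)
  up <- maxunpool2x2(r$values, r$indices, c(4, 4))
  expect_equal(sum(up != 0), 4)
  bad <- r$indices; bad[1, 1, 1, 1] <- 16L  # points outside its window
  expect_error(maxunpool2x2(r$values, bad, c(4, 4)), "window")
})

test_that("pixelwise softmax is normalized, symmetric and overflow-safe", {
  z <- array(0, c(1, 4, 2, 2))
  expect_true(all(abs(softmax_pixelwise(z) - 0.25) < 1e-15))
  big <- array(0, c(1, 4, 1, 1)); big[1, 1, 1, 1] <- 1000
  s <- softmax_pixelwise(big)
  expect_true(all(is.finite(s)))
  expect_equal(s[1, 1, 1, 1], 1)
  x <- rand_tensor(2, 4, 6, 6, sd = 5)
  sums <- apply(softmax_pixelwise(x), c(1, 3, 4), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("label decisions take the per-pixel argmax with background ties", {
  lab <- matrix(sample(0:3, 36, TRUE), 6, 6)
  onehot <- array(0, c(1, 4, 6, 6))
  for (k in 0:3) onehot[1, k + 1, , ] <- (lab == k) * 1
  expect_identical(predict_labels(onehot)[[1]], lab)
  flat <- array(0.25, c(1, 4, 3, 3))
  expect_true(all(predict_labels(flat)[[1]] == 0L))
  set.seed(3)
  p <- softmax_pixelwise(rand_tensor(2, 4, 5, 5))
  expect_identical(predict_labels(p), oracle_argmax_labels(p))
})
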