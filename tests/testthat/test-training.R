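test_that("median-frequency weights follow the closed-form definition", {
  lab_eq <- matrix(rep(0:3, each = 4), 4, 4)
  expect_equal(unname(compute_class_weights(lab_eq)), rep(1, 4))

  # frequencies (0.5, 0.25, 0.15, 0.1) over a 400-pixel map; median 0.2
  lab <- matrix(rep(0:3, times = c(200, 100, 60, 40)), 20, 20)
  expect_equal(unname(compute_class_weights(lab)),
               c(0.4, 0.8, 4 / 3, 2), tolerance = 1e-12)

  p <- generate_phantom(phantom_spec(seed = 2))
  w <- compute_class_weights(p$labels)
  f <- class_frequencies(p$labels)
  expect_lt(w[["background"]], 1)
  expect_gt(w[[names(which.min(f))]], 1)
  expect_error(compute_class_weights(matrix(0L, 4, 4)), "absent")
  expect_equal(unname(compute_class_weights(matrix(0L, 4, 4), "uniform")),
               rep(1, 4))
})

test_that("weighted cross-entropy matches closed forms and the loop oracle", {
  lab <- matrix(sample(0:3, 64, TRUE), 8, 8)
  onehot <- array(0, c(1, 4, 8, 8))
  for (k in 0:3) onehot[1, k + 1, , ] <- (lab == k) * 1
  w <- rep(1, 4)
  expect_lt(weighted_cross_entropy(onehot, lab, w), 1e-6)

  unif <- array(0.25, c(1, 4, 8, 8))
  expect_equal(weighted_cross_entropy(unif, lab, w), log(4), tolerance = 1e-12)

  set.seed(5)
  probs <- softmax_pixelwise(rand_tensor(2, 4, 6, 6))
  truth <- list(matrix(sample(0:3, 36, TRUE), 6, 6),
                matrix(sample(0:3, 36, TRUE), 6, 6))
  wts <- c(0.5, 1.2, 0.8, 2)
  loop <- 0
  for (n in 1:2) for (h in 1:6) for (q in 1:6) {
    y <- truth[[n]][h, q]
    loop <- loop - wts[y + 1] * log(probs[n, y + 1, h, q])
  }
  expect_equal(weighted_cross_entropy(probs, truth, wts), loop / 72,
               tolerance = 1e-10)
})

test_that("gradients vanish when every represented class has zero weight", {
  arch <- build_architecture(2)
  params <- init_params(arch, 3)
  p <- generate_phantom(tiny_spec(seed = 4))
  present <- sort(unique(as.integer(p$labels)))
  w <- rep(1, 4); w[present + 1] <- 0
  lg <- loss_gradients(params, arch, list(zero_center(p$image)),
                       list(p$labels), w)
  expect_equal(lg$loss, 0)
  expect_true(all(vapply(lg$grads, function(g) max(abs(g)), 0) < 1e-14))
})

test_that("duplicating a batch leaves the mean-normalized gradient unchanged", {
  arch <- build_architecture(2)
  params <- init_params(arch, 6)
  p <- generate_phantom(tiny_spec(seed = 8))
  img <- zero_center(p$image)
  w <- compute_class_weights(p$labels)
  g1 <- loss_gradients(params, arch, list(img), list(p$labels), w)$grads
  g2 <- loss_gradients(params, arch, list(img, img),
                       list(p$labels, p$labels), w)$grads
  for (nm in names(g1))
    expect_equal(g2[[nm]], g1[[nm]], tolerance = 1e-10)
})

test_that("augmentation preserves shapes and the label alphabet", {
  p <- generate_phantom(tiny_spec(seed = 9))
  set.seed(1)
  ident <- augment_pair(p$image, p$labels, rotation_range = 0, reflect = FALSE)
  expect_identical(ident$image, p$image)
  expect_identical(ident$labels, p$labels)
  set.seed(2)
  for (i in 1:10) {
    a <- augment_pair(p$image, p$labels)
    expect_identical(dim(a$image), dim(p$image))
    expect_identical(dim(a$labels), dim(p$labels))
    expect_true(all(a$labels %in% 0:3))
  }
})

test_that("mirroring twice is the identity", {
  p <- generate_phantom(tiny_spec(seed = 10))
  flip <- function(m) m[, rev(seq_len(ncol(m)))]
  expect_identical(flip(flip(p$image)), p$image)
  # force two flip draws through the augmenter (rotation disabled)
  set.seed(101)
  draws <- replicate(50, {
    a <- augment_pair(p$image, p$labels, rotation_range = 0)
    identical(a$image, p$image) || identical(a$image, flip(p$image))
  })
  expect_true(all(draws))
})

test_that("momentum updates follow the velocity recursion", {
  arch <- build_architecture(1)
  params <- init_params(arch, 1)
  flat <- coef(structure(list(params = params), class = "segnet"))
  g <- lapply(flat, function(a) array(1, dim(a) %||% length(a)))
  names(g) <- names(flat)

  s1 <- sgdm_step(params, g, NULL, lr = 0.1, momentum = 0)
  f1 <- brainseg:::trainable_list(s1$params)
  expect_equal(f1[[1]], flat[[1]] - 0.1, tolerance = 1e-14)

  s <- sgdm_step(params, g, NULL, lr = 0.1, momentum = 0.9)
  s <- sgdm_step(s$params, g, s$state, lr = 0.1, momentum = 0.9)
  f2 <- brainseg:::trainable_list(s$params)
  expect_equal(f2[[1]], flat[[1]] - 0.29, tolerance = 1e-12)

  z <- lapply(g, function(a) array(0, dim(a) %||% length(a)))
  sz <- sgdm_step(params, z, NULL, lr = 0.5, momentum = 0.9)
  expect_equal(brainseg:::trainable_list(sz$params), flat, tolerance = 0)
})

test_that("the epoch loop books minibatches and reproduces under one seed", {
  d <- generate_dataset(16, tiny_spec(), seed = 31, split_fraction = 0.875)
  fit <- segnet(c(d$train, d$test), filter_width = 2, epochs = 1,
                batch_size = 8, seed = 31)
  expect_identical(nrow(fit$history), 1L)
  fit2 <- segnet(c(d$train, d$test), filter_width = 2, epochs = 1,
                 batch_size = 8, seed = 31)
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$history[c("epoch", "loss", "accuracy")],
                   fit2$history[c("epoch", "loss", "accuracy")])
})

test_that("a reduced network overfits a handful of phantoms", {
  d <- generate_dataset(4, phantom_spec(height = 24, width = 24,
                                        n_ventricles = 1L), seed = 77,
                        split_fraction = 0.5)
  pairs <- c(d$train, d$test)
  fit <- segnet(pairs, filter_width = 4, epochs = 200, batch_size = 4,
                seed = 77, augment = FALSE, patience = 1000L,
                learning_rate = 0.05)
  expect_gt(fit$history$accuracy[nrow(fit$history)], 0.95)
})
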