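test_that("the layer list matches the reference table", {
  arch <- build_architecture()
  expect_length(arch$layers, 31)
  expect_identical(arch$layers[[27]]$name, "decoder1_conv1")
  expect_identical(arch$layers[[27]]$out_channels, 4L)
  expect_identical(arch$layers[[2]]$in_channels, 1L)
  expect_identical(arch$layers[[2]]$out_channels, 64L)
  expect_identical(arch$layers[[30]]$type, "softmax")
  expect_identical(arch$layers[[31]]$type, "pixel_classification")
  expect_identical(unname(arch$pairings),
                   c("decoder1_unpool", "decoder2_unpool"))
  # 8 convolutions and 8 batch norms mirror the encoder/decoder symmetry
  types <- vapply(arch$layers, `[[`, "", "type")
  expect_identical(sum(types == "conv"), 8L)
  expect_identical(sum(types == "bn"), 8L)
})

test_that("the full-width network has 225,420 trainable scalars", {
  params <- init_params(build_architecture(64), seed = 1)
  expect_identical(count_trainable(params), 225420L)
  # independent shape sum over the layer table
  arch <- build_architecture(64)
  manual <- 0L
  for (l in arch$layers) {
    if (l$type == "conv") manual <- manual + l$out_channels * (l$in_channels * 9L + 1L)
    if (l$type == "bn") manual <- manual + 2L * l$channels
  }
  expect_identical(manual, 225420L)
})

test_that("initialization is seeded, fan-in scaled, and unit-gamma", {
  a <- init_params(build_architecture(8), seed = 5)
  b <- init_params(build_architecture(8), seed = 5)
  expect_identical(a, b)
  expect_true(all(a$encoder1_bn_1$gamma == 1))
  expect_true(all(a$encoder1_bn_1$beta == 0))
  expect_true(all(a$encoder1_conv1$b == 0))
  full <- init_params(build_architecture(64), seed = 9)
  v <- stats::var(as.numeric(full$encoder2_conv1$W))  # 36,864 draws
  expect_lt(abs(v - 2 / (9 * 64)) / (2 / (9 * 64)), 0.2)
})

test_that("the forward pass conserves shape and normalizes per pixel", {
  arch <- build_architecture(4)
  params <- init_params(arch, 2)
  x <- rand_tensor(2, 1, 16, 16)
  out <- segnet_forward(params, arch, x, "train")
  expect_identical(dim(out$probs), c(2L, 4L, 16L, 16L))
  sums <- apply(out$probs, c(1, 3, 4), sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # a non-square canvas divisible by 4 passes through unchanged in size
  x2 <- rand_tensor(1, 1, 24, 32)
  out2 <- segnet_forward(params, arch, x2, "train")
  expect_identical(dim(out2$probs), c(1L, 4L, 24L, 32L))
  expect_error(segnet_forward(params, arch, rand_tensor(1, 1, 18, 16), "train"),
               "divisible by 4")
})

test_that("inference mode is pure: repeated calls agree bitwise", {
  arch <- build_architecture(4)
  params <- init_params(arch, 3)
  x <- rand_tensor(2, 1, 16, 16)
  params <- segnet_forward(params, arch, x, "train")$params  # prime running stats
  o1 <- segnet_forward(params, arch, x, "infer")
  o2 <- segnet_forward(params, arch, x, "infer")
  expect_identical(o1$probs, o2$probs)
  expect_identical(o1$params, params)
})

test_that("a reduced network can memorize one phantom", {
  p <- generate_phantom(tiny_spec(seed = 55))
  # a deliberately hot learning rate: this checks that the machinery can
  # memorize a single slice, not the reference training schedule
  fit <- segnet(list(p), filter_width = 4, epochs = 200, batch_size = 1,
                seed = 55, augment = FALSE, patience = 1000L,
                learning_rate = 0.05)
  pred <- predict(fit, p$image)
  expect_gte(mean(pred == p$labels), 0.99)
})
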