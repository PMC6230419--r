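test_that("Dice and Jaccard follow their set definitions", {
  m <- matrix(FALSE, 5, 5)
  x <- m; x[1:2, 1:2] <- TRUE            # |x| = 4
  y <- m; y[1:2, 1:3] <- TRUE            # |y| = 6, |x ∩ y| = 4
  x[1, 1] <- FALSE; x[3, 3] <- TRUE      # now |x| = 4, |x ∩ y| = 3
  expect_equal(dice(x, y), 2 * 3 / (4 + 6))
  expect_equal(jaccard(x, y), 3 / 7)

  z <- m; z[4:5, 4:5] <- TRUE
  expect_equal(dice(x, x), 1)
  expect_equal(dice(z, y), 0)
  expect_equal(dice(m, m), 1)            # both empty
  expect_equal(jaccard(m, m), 1)
  expect_error(dice(x, matrix(TRUE, 2, 2)), "identical shapes")
})

test_that("J = D / (2 - D) holds to machine precision and metrics are symmetric", {
  set.seed(13)
  for (i in 1:200) {
    a <- matrix(stats::runif(64) < stats::runif(1), 8, 8)
    b <- matrix(stats::runif(64) < stats::runif(1), 8, 8)
    D <- dice(a, b); J <- jaccard(a, b)
    expect_equal(J, D / (2 - D), tolerance = 1e-14)
    expect_identical(dice(a, b), dice(b, a))
    expect_identical(jaccard(a, b), jaccard(b, a))
  }
})

test_that("growing the intersection at fixed cardinalities never lowers overlap", {
  # masks with |x| = |y| = 8 and increasing intersection
  prev_d <- -1; prev_j <- -1
  for (k in 2:8) {
    x <- matrix(FALSE, 4, 4); y <- matrix(FALSE, 4, 4)
    x[seq_len(8)] <- TRUE
    y[seq.int(9 - k, 16 - k)] <- TRUE
    expect_gte(dice(x, y), prev_d)
    expect_gte(jaccard(x, y), prev_j)
    prev_d <- dice(x, y); prev_j <- jaccard(x, y)
  }
})

test_that("gray rendering uses equally spaced levels and inverts exactly", {
  lab <- matrix(c(0L, 1L, 2L, 3L), 2, 2)
  g <- label_to_gray(lab)
  expect_identical(sort(unique(as.numeric(g))), c(0, 85, 170, 255))
  expect_identical(gray_to_label(g), lab)
  expect_true(all(label_to_gray(matrix(0L, 3, 3)) == 0))
  expect_error(label_to_gray(matrix(4L, 2, 2)), "outside")
})

test_that("intensity MSE matches the double-loop definition", {
  a <- matrix(100, 4, 4)
  expect_equal(mse_image(a, a), 0)
  expect_equal(mse_image(a, a + 2), 4)
  set.seed(17)
  for (i in 1:5) {
    x <- matrix(sample(0:255, 64, TRUE), 8, 8)
    y <- matrix(sample(0:255, 64, TRUE), 8, 8)
    expect_equal(mse_image(x, y), oracle_mse(x, y))
    expect_identical(mse_image(x, y), mse_image(y, x))
  }
})

test_that("confusion matrices tally every pixel once", {
  lab <- matrix(sample(0:3, 100, TRUE), 10, 10)
  cm <- confusion_matrix4(lab, lab)
  expect_true(all(cm[upper.tri(cm) | lower.tri(cm)] == 0))
  expect_equal(sum(cm), 100)
  set.seed(19)
  for (i in 1:5) {
    p <- matrix(sample(0:3, 64, TRUE), 8, 8)
    t <- matrix(sample(0:3, 64, TRUE), 8, 8)
    cm <- confusion_matrix4(p, t)
    expect_identical(unname(unclass(cm)), oracle_confusion(p, t))
    expect_equal(unname(rowSums(cm)),
                 as.numeric(tabulate(as.integer(t) + 1L, 4)))
  }
})

test_that("confusion-matrix statistics reproduce a hand-tallied toy case", {
  pred <- matrix(c(rep(0L, 3), rep(1L, 1), rep(0L, 2), rep(1L, 4)), 1, 10)
  truth <- matrix(c(rep(0L, 4), rep(1L, 6)), 1, 10)
  st <- cm_statistics(confusion_matrix4(pred, truth))
  expect_equal(st$global_accuracy, 0.7)
  expect_equal(unname(st$class_accuracy[1]), 0.75)

  perfect <- cm_statistics(confusion_matrix4(truth, truth))
  expect_equal(perfect$global_accuracy, 1)
  expect_equal(perfect$mean_accuracy, 1)
  expect_equal(perfect$mean_iou, 1)
  expect_equal(perfect$weighted_iou, 1)
  expect_error(cm_statistics(matrix(0, 4, 4)), "empty")
})

test_that("per-class IoU from the confusion matrix equals mask Jaccard", {
  set.seed(23)
  for (i in 1:20) {
    p <- matrix(sample(0:3, 144, TRUE), 12, 12)
    t <- matrix(sample(0:3, 144, TRUE), 12, 12)
    st <- cm_statistics(confusion_matrix4(p, t))
    for (k in 0:3)
      expect_equal(unname(st$class_iou[k + 1]), jaccard(p == k, t == k),
                   tolerance = 1e-14)
  }
})

test_that("boundary-F1 rewards near-coincident contours", {
  m <- matrix(FALSE, 16, 16)
  sq <- m; sq[5:10, 5:10] <- TRUE
  expect_equal(bf_score(sq, sq), 1)
  far <- m; far[14:16, 14:16] <- TRUE
  near0 <- m; near0[1:3, 1:3] <- TRUE
  expect_equal(bf_score(near0, far, tolerance = 2), 0)
  shifted <- m; shifted[6:11, 5:10] <- TRUE
  expect_equal(bf_score(sq, shifted, tolerance = 2),
               oracle_bf(sq, shifted, 2))
  set.seed(29)
  for (i in 1:5) {
    a <- matrix(stats::runif(64) < 0.4, 8, 8)
    b <- matrix(stats::runif(64) < 0.4, 8, 8)
    expect_equal(bf_score(a, b, tolerance = 1), oracle_bf(a, b, 1))
  }
  expect_equal(bf_score(m, m), 1)
  expect_equal(bf_score(sq, m), 0)
})

test_that("the full report is self-consistent and exact on identical maps", {
  p <- generate_phantom(phantom_spec(height = 32, width = 32, seed = 41))
  r <- evaluate_segmentation(p$labels, p$labels)
  expect_true(all(r$per_class$dice == 1))
  expect_true(all(r$per_class$jaccard == 1))
  expect_equal(r$global_accuracy, 1)
  expect_equal(r$mse, 0)

  q <- generate_phantom(phantom_spec(height = 32, width = 32, seed = 43))
  r2 <- evaluate_segmentation(q$labels, p$labels)
  expect_equal(r2$per_class$jaccard,
               r2$per_class$dice / (2 - r2$per_class$dice), tolerance = 1e-12)
  expect_equal(r2$mean_dice_tissue, mean(r2$per_class$dice[2:4]))
  expect_true(all(r2$per_class$iou >= 0 & r2$per_class$iou <= 1))
  js <- report_to_json(r2)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$global_accuracy, r2$global_accuracy)
})
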