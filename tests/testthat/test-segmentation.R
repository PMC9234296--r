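test_that("cluster centers initialize deterministically from the intensity range", {
  img255 <- matrix(c(0, 255), 1, 2)
  expect_equal(init_centers(img255, 3), c(64, 128, 192))
  expect_equal(init_centers(img255, 1), 128)
  img99 <- matrix(c(10, 99), 1, 2)
  expect_equal(init_centers(img99, 4), c(20, 40, 60, 80))
  expect_true(all(diff(init_centers(img255, 5)) > 0))
  expect_error(init_centers(img255, 0), ">= 1")
})

test_that("hybrid clustering separates well-separated intensities", {
  img <- matrix(rep(c(20, 200), each = 50), 10, 10)
  cl <- hybrid_cluster(img, M = 2)
  expect_equal(cl$centers, c(20, 200), tolerance = 1e-6)
  # each pixel's membership concentrates on its own cluster
  own <- ifelse(as.vector(img) == 20, 1L, 2L)
  picked <- max.col(cl$memberships)
  expect_true(all(picked == own))
  expect_gt(min(cl$memberships[cbind(seq_along(own), own)]), 0.99)
})

test_that("hybrid clustering memberships are normalized and objective non-increasing", {
  s <- generate_phantom(phantom_spec("benign", seed = 9))
  pre <- idad_despeckle(s$image)
  cl <- suppressMessages(hybrid_cluster(pre))
  expect_true(all(abs(rowSums(cl$memberships) - 1) < 1e-9))
  expect_true(all(diff(cl$objective) <= 1e-6 * cl$objective[1]))
  expect_true(all(diff(cl$centers) > 0))

  # lesion pixels dominate the lowest-center cluster
  lesion_label <- cl$labels[s$mask == 1]
  expect_gt(mean(lesion_label == 1), 0.95)

  # deterministic: same image gives bit-identical results
  cl2 <- suppressMessages(hybrid_cluster(pre))
  expect_identical(cl$centers, cl2$centers)
  expect_identical(cl$labels, cl2$labels)
})

test_that("degenerate constant image follows the empty-cluster path", {
  cimg <- matrix(80, 8, 8)
  expect_message(cl <- hybrid_cluster(cimg, M = 2), "re-seeded")
  expect_equal(length(unique(as.vector(cl$labels))), 1L)
})

test_that("binarization keeps the hypoechoic cluster as a clean mask", {
  img <- matrix(200, 30, 30)
  img[10:20, 10:20] <- 20
  cl <- hybrid_cluster(img, M = 2)
  mask <- binarize_lesion(cl, img)
  truth <- matrix(0L, 30, 30); truth[10:20, 10:20] <- 1L
  expect_equal(mask, truth)

  # phantom: Dice against truth before refinement
  s <- generate_phantom(phantom_spec("benign", seed = 3))
  pre <- idad_despeckle(s$image)
  cl2 <- suppressMessages(hybrid_cluster(pre))
  m <- binarize_lesion(cl2, pre)
  expect_gte(dice(m, s$mask), 0.85)

  # no lesion-cluster support signals a segmentation failure
  fake <- cl
  fake$labels <- matrix(2L, 30, 30)
  expect_error(binarize_lesion(fake, img), "segmentation failure")
})

test_that("level-set refinement recovers the true region from bad initializations", {
  tl <- two_level_disk_image()
  # far-off small square grows to the disk
  m0 <- matrix(0L, 96, 96); m0[40:52, 40:52] <- 1L
  ref <- level_set_refine(m0, tl$image, max_iter = 800)
  expect_gte(dice(ref$mask, tl$truth), 0.98)
  # oversized disk shrinks back
  m1 <- digital_disk(96, 35)
  ref1 <- level_set_refine(m1, tl$image, max_iter = 800)
  expect_gte(dice(ref1$mask, tl$truth), 0.98)
})

test_that("level-set refinement respects its boundary-value contracts", {
  tl <- two_level_disk_image()
  # initialization at the energy minimum barely changes
  ref <- level_set_refine(tl$truth, tl$image, max_iter = 200)
  expect_lte(mean(ref$mask != tl$truth), 0.01)
  # zero budget is the identity
  ref0 <- level_set_refine(tl$truth, tl$image, max_iter = 0)
  expect_identical(ref0$mask, tl$truth)
  # signed field is negative inside
  expect_true(all(ref0$phi[tl$truth == 1] <= 0))
  expect_error(level_set_refine(matrix(0L, 9, 9), matrix(1, 9, 9)), "empty")
})

test_that("refinement never decreases Dice on speckled phantoms", {
  for (sd in c(4, 8)) {
    s <- generate_phantom(phantom_spec("malignant", seed = sd))
    pre <- idad_despeckle(s$image)
    seg <- suppressMessages(segment_lesion(pre))
    expect_gte(dice(seg$mask, s$mask), dice(seg$initial_mask, s$mask))
  }
})

test_that("ROI extraction crops the bounding box with margin", {
  img <- matrix(runif(900), 30, 30)
  full <- matrix(1L, 30, 30)
  expect_equal(extract_roi(full, img)$roi, img)

  single <- matrix(0L, 30, 30); single[10, 10] <- 1L
  r <- extract_roi(single, img, margin = 2)
  expect_identical(dim(r$roi), c(5L, 5L))
  expect_equal(unname(r$bbox), c(8L, 12L, 8L, 12L))

  # clipping at the border
  corner <- matrix(0L, 30, 30); corner[1, 1] <- 1L
  rc <- extract_roi(corner, img, margin = 3)
  expect_identical(dim(rc$roi), c(4L, 4L))

  s <- generate_phantom(phantom_spec("benign", seed = 6))
  pre <- idad_despeckle(s$image)
  seg <- suppressMessages(segment_lesion(pre))
  rp <- extract_roi(seg$mask, pre)
  inside_box <- s$mask[rp$bbox["row_min"]:rp$bbox["row_max"],
                       rp$bbox["col_min"]:rp$bbox["col_max"]]
  expect_gte(sum(inside_box) / sum(s$mask), 0.99)

  expect_error(extract_roi(matrix(0L, 5, 5), matrix(1, 5, 5)), "empty")
})

test_that("segmentation of a seeded phantom is bit-reproducible", {
  s <- generate_phantom(phantom_spec("malignant", seed = 12))
  pre <- idad_despeckle(s$image)
  a <- suppressMessages(segment_lesion(pre))
  b <- suppressMessages(segment_lesion(pre))
  expect_identical(a$mask, b$mask)
})
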