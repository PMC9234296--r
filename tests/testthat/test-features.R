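test_that("morphology of canonical shapes matches geometry", {
  sq <- matrix(0L, 20, 20); sq[6:15, 6:15] <- 1L
  m <- morphological_features(sq)
  expect_equal(unname(m["area"]), 100)
  expect_equal(unname(m["solidity"]), 1)
  expect_equal(unname(m["extent"]), 1)

  disk <- digital_disk(101, 30)
  md <- morphological_features(disk)
  expect_gte(unname(md["circularity"]), 0.90)
  expect_lte(unname(md["circularity"]), 1.10)
  expect_lt(unname(md["eccentricity"]), 0.1)

  # spiculated star has strictly lower circularity than a matched ellipse
  star <- generate_phantom(phantom_spec("malignant", seed = 2))$mask
  ellipse <- generate_phantom(phantom_spec("benign", seed = 2))$mask
  expect_lt(morphological_features(star)["circularity"],
            morphological_features(ellipse)["circularity"])

  expect_error(morphological_features(matrix(0L, 5, 5)), "empty")
})

test_that("rotation/translation invariance and area scaling hold", {
  s <- generate_phantom(phantom_spec("malignant", seed = 5))
  m0 <- morphological_features(s$mask)
  rot <- s$mask[nrow(s$mask):1, ]  # 90-degree rotation of the grid
  m90 <- morphological_features(t(rot))
  for (f in c("area", "circularity", "solidity")) {
    expect_equal(unname(m0[f]), unname(m90[f]), tolerance = 1e-6)
  }

  # translation: shift the lesion inside a larger frame
  big <- matrix(0L, 160, 160)
  big[11:138, 21:148] <- s$mask
  mt <- morphological_features(big)
  expect_equal(unname(m0), unname(mt), tolerance = 1e-9)

  # 2x upsampling multiplies area by 4
  up <- s$mask[rep(seq_len(128), each = 2), rep(seq_len(128), each = 2)]
  expect_equal(unname(morphological_features(up)["area"]),
               4 * unname(m0["area"]))
})

test_that("co-occurrence features follow the Haralick definitions", {
  # constant region: single co-occurrence cell
  g <- glcm_features(matrix(5, 4, 4), matrix(1L, 4, 4))
  expect_equal(unname(g["energy_0"]), 1)
  expect_equal(unname(g["contrast_0"]), 0)
  expect_equal(unname(g["entropy_0"]), 0)

  # 2x2 checkerboard at the horizontal offset: contrast exactly 1
  cb <- matrix(c(0, 100, 100, 0), 2, 2)
  gc <- glcm_features(cb, matrix(1L, 2, 2), levels = 2)
  expect_equal(unname(gc["contrast_0"]), 1)
  expect_equal(unname(gc["correlation_0"]), -1, tolerance = 1e-9)

  # correlation bounded in [-1, 1] for arbitrary regions
  set.seed(4)
  for (i in 1:5) {
    r <- matrix(runif(100, 0, 255), 10, 10)
    gr <- glcm_features(r, matrix(1L, 10, 10))
    corr <- gr[grepl("^correlation", names(gr))]
    expect_true(all(corr >= -1 - 1e-9 & corr <= 1 + 1e-9))
    expect_true(all(gr[grepl("^energy", names(gr))] <= 1 + 1e-9))
  }

  expect_error(glcm_features(matrix(1, 3, 3), matrix(1L, 4, 4)), "mismatch")
})

test_that("first-order moments use the population convention", {
  roi <- matrix(c(0, 0, 10, 10), 2, 2)
  f <- first_order_features(roi, matrix(1L, 2, 2))
  expect_equal(unname(f["fo_mean"]), 5)
  expect_equal(unname(f["fo_variance"]), 25)
  expect_equal(unname(f["fo_skewness"]), 0)

  fc <- first_order_features(matrix(3, 3, 3), matrix(1L, 3, 3))
  expect_equal(unname(fc[c("fo_variance", "fo_skewness", "fo_kurtosis")]),
               c(0, 0, 0))

  one_px <- matrix(0L, 3, 3); one_px[1, 1] <- 1L
  expect_error(first_order_features(matrix(3, 3, 3), one_px), "2 pixels")
})

test_that("feature fusion follows the documented schema", {
  s <- generate_phantom(phantom_spec("benign", seed = 8))
  roi <- extract_roi(s$mask, s$image)
  v <- fuse_features(morphological_features(roi$mask),
                     glcm_features(roi$roi, roi$mask),
                     first_order_features(roi$roi, roi$mask))
  expect_length(v, 33)
  expect_identical(names(v), feature_schema())
  # deterministic
  v2 <- extract_features(roi$roi, roi$mask)
  expect_identical(v, v2)
  # out-of-order parts are rejected
  expect_error(fuse_features(glcm_features(roi$roi, roi$mask),
                             morphological_features(roi$mask),
                             first_order_features(roi$roi, roi$mask)),
               "schema")
})

test_that("standardization statistics come from training rows only", {
  set.seed(5)
  tr <- matrix(rnorm(60, 10, 3), 20, 3)
  te <- matrix(rnorm(30, 10, 3), 10, 3)
  st <- standardize_fit(tr)
  z <- standardize_apply(tr, st)
  expect_equal(unname(colMeans(z)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(z, 2, sd)), c(1, 1, 1), tolerance = 1e-12)
  # test rows standardized with stored training stats reproducibly
  expect_identical(standardize_apply(te, st), standardize_apply(te, st))
})

test_that("PCA retains the smallest sufficient component count", {
  # rank-1 data: one component explains everything
  t_line <- cbind(1:10, 2 * (1:10))
  p <- pca_fit_transform(t_line, 0.95)
  expect_equal(p$model$k, 1L)
  expect_equal(p$model$ratios[1], 1, tolerance = 1e-12)

  set.seed(6)
  x <- matrix(rnorm(500), 50, 10)
  p2 <- pca_fit_transform(scale(x), 0.95)
  expect_equal(sum(p2$model$ratios), 1, tolerance = 1e-12)
  # residual variance from retained components at most 5%
  expect_lte(1 - sum(p2$model$ratios[seq_len(p2$model$k)]), 0.05)
  # projected training columns are uncorrelated
  cv <- cov(p2$scores)
  expect_lt(max(abs(cv[upper.tri(cv)])), 1e-8)
  # transform reproduces the fitted scores
  expect_equal(pca_transform(p2$model, scale(x)), p2$scores,
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(pca_fit_transform(x, 0), "retained_variance")
  expect_error(pca_fit_transform(x, 1.2), "retained_variance")
})
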