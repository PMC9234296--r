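test_that("sigmoid enhancement matches the closed form and stays in range", {
  img <- matrix(c(0, 255), 1, 2)
  out <- sigmoid_enhance(img, alpha = 4, gamma = 7)
  expect_equal(out[1, 1], 255 / (1 + exp(4 / 7)), tolerance = 1e-12)
  expect_equal(out[1, 1], 92.0, tolerance = 1e-2)
  expect_equal(out[1, 2], 255 / (1 + exp(-251 / 7)), tolerance = 1e-12)
  expect_gt(out[1, 2], 254.9)

  # constant image: scaled term vanishes, output identically mn
  cimg <- matrix(42, 5, 5)
  expect_equal(sigmoid_enhance(cimg), cimg)

  # monotone and bounded for arbitrary images
  set.seed(1)
  r <- matrix(runif(400, 0, 255), 20, 20)
  e <- sigmoid_enhance(r)
  expect_true(all(e >= min(r) - 1e-9 & e <= max(r) + 1e-9))
  o <- order(r)
  expect_true(all(diff(e[o]) >= -1e-12))
  expect_identical(dim(e), dim(r))
})

test_that("sigmoid enhancement rejects invalid inputs", {
  expect_error(sigmoid_enhance(matrix(c(1, NA), 1, 2)), "non-finite")
  expect_error(sigmoid_enhance(matrix(c(1, Inf), 1, 2)), "non-finite")
  expect_error(sigmoid_enhance(matrix(1, 2, 2), gamma = 0), "gamma")
  expect_error(sigmoid_enhance(matrix(1, 2, 2), gamma = -3), "gamma")
})

test_that("median filter replaces pixels by neighborhood medians", {
  patch <- matrix(1:9, 3, 3)
  expect_equal(median_filter(patch)[2, 2], 5)

  cimg <- matrix(7, 6, 6)
  expect_equal(median_filter(cimg), cimg)

  # single impulse on uniform background disappears
  imp <- matrix(10, 7, 7); imp[4, 4] <- 200
  expect_equal(median_filter(imp), matrix(10, 7, 7))

  # output values always belong to the input's value set
  set.seed(2)
  r <- matrix(sample(c(3, 8, 11, 250), 100, replace = TRUE), 10, 10)
  expect_true(all(median_filter(r) %in% unique(as.vector(r))))
  expect_true(all(median_filter(r, 5) %in% unique(as.vector(r))))
})

test_that("median filter rejects even or oversized kernels", {
  expect_error(median_filter(matrix(1, 5, 5), kernel = 4), "odd")
  expect_error(median_filter(matrix(1, 5, 5), kernel = 2), "odd")
  expect_error(median_filter(matrix(1, 5, 5), kernel = 7), "larger")
})

test_that("constructive combination is the element-wise maximum", {
  a <- matrix(c(1, 3, 5, 2), 2, 2)
  b <- matrix(c(2, 3, 4, 3), 2, 2)
  expect_equal(combine_constructive(a, b), matrix(c(2, 3, 5, 3), 2, 2))
  expect_equal(combine_constructive(a, a), a)
  z <- matrix(0, 2, 2)
  expect_equal(combine_constructive(z, a), a)
  out <- combine_constructive(a, b)
  expect_true(all(out >= a) && all(out >= b))
  expect_error(combine_constructive(a, matrix(1, 3, 2)), "shape")
})

test_that("anisotropic diffusion smooths flats and keeps edges", {
  img <- matrix(runif(15 * 15, 99, 101), 15, 15)
  expect_equal(perona_malik_diffuse(img, iterations = 0), img)
  cimg <- matrix(5, 10, 10)
  expect_equal(perona_malik_diffuse(cimg, iterations = 25), cimg)

  # step edge: contrast retained within 10%, flat-region variance drops
  step_img <- cbind(matrix(100, 20, 10), matrix(200, 20, 10)) +
    matrix(rnorm(400, 0, 2), 20, 20)
  out <- perona_malik_diffuse(step_img, iterations = 20, kappa = 10, step = 0.2)
  contrast_in <- mean(step_img[, 11:20]) - mean(step_img[, 1:10])
  contrast_out <- mean(out[, 11:20]) - mean(out[, 1:10])
  expect_gt(contrast_out, 0.9 * contrast_in)
  expect_lt(var(as.vector(out[, 1:9])), var(as.vector(step_img[, 1:9])))

  # extremum-diminishing: range never expands
  expect_gte(min(out), min(step_img))
  expect_lte(max(out), max(step_img))

  expect_error(perona_malik_diffuse(cimg, step = 0.3), "0.25")
  expect_error(perona_malik_diffuse(cimg, step = 0), "0.25")
  expect_error(perona_malik_diffuse(cimg, kappa = -1), "kappa")
})

test_that("IDAD despeckling reduces homogeneous-region variation", {
  cimg <- matrix(33, 12, 12)
  expect_equal(idad_despeckle(cimg), cimg)

  # speckled phantom: background variance strictly decreases
  s <- generate_phantom(phantom_spec("benign", seed = 5))
  out <- idad_despeckle(s$image)
  bg <- s$mask == 0
  expect_lt(var(out[bg]), var(s$image[bg]))
  expect_identical(dim(out), dim(s$image))

  # coefficient of variation in the homogeneous background drops too
  cov_in <- sd(s$image[bg]) / mean(s$image[bg])
  cov_out <- sd(out[bg]) / mean(out[bg])
  expect_lt(cov_out, cov_in)

  # single impulse: amplitude reduced relative to input
  imp <- matrix(10, 5, 5); imp[3, 3] <- 100
  out_imp <- idad_despeckle(imp, iterations = 5)
  expect_lt(out_imp[3, 3] - 10, 90)
})

test_that("every preprocessing stage preserves image shape", {
  set.seed(3)
  img <- matrix(runif(13 * 17, 0, 255), 13, 17)
  for (f in list(function(x) sigmoid_enhance(x),
                 function(x) median_filter(x),
                 function(x) combine_constructive(x, x),
                 function(x) perona_malik_diffuse(x, iterations = 3),
                 function(x) idad_despeckle(x, iterations = 3),
                 function(x) preprocess_image(x, iterations = 3))) {
    expect_identical(dim(f(img)), c(13L, 17L))
  }
})
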