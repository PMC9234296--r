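test_that("Haar family members evaluate per the breakpoint formulas", {
  b <- haar_basis(1)
  # i = 2 (j = 0, k = 0): breakpoints (0, 0.5, 1)
  expect_equal(haar_eval(b, 2, 0.25), -1)
  expect_equal(haar_eval(b, 2, 0.75), 1)
  expect_equal(haar_eval(b, 2, 1.5), 0)
  # scaling function is 1 on the whole interval
  expect_equal(haar_eval(b, 1, 0.3), 1)
  expect_equal(haar_eval(b, 1, -0.1), 0)
  expect_error(haar_eval(b, 3, 0.5), "out of range")
  expect_error(haar_basis(3), "power of two")

  # breakpoints tile the interval at every level
  b4 <- haar_basis(4)
  for (j in unique(b4$table$j)) {
    rows <- b4$table[b4$table$j == j, ]
    expect_equal(rows$xi1[1], 0)
    expect_equal(rows$xi3[nrow(rows)], 1)
    if (nrow(rows) > 1) expect_equal(rows$xi1[-1], rows$xi3[-nrow(rows)])
  }
})

test_that("Haar family is orthogonal under cell quadrature", {
  for (M in c(2L, 4L)) {
    b <- haar_basis(M)
    mid <- b$A + (seq_len(2 * M) - 0.5) * b$dx
    H <- sapply(seq_len(2 * M), function(i) haar_eval(b, i, mid))
    G <- t(H) %*% H * b$dx
    expect_lt(max(abs(G[upper.tri(G)])), 1e-12)
    expect_true(all(diag(G) > 0))
  }
})

test_that("Haar expansion reconstructs dyadic piecewise constants exactly", {
  b <- haar_basis(4)
  t <- seq(0.001, 0.999, length.out = 400)
  # a wavelet is its own expansion
  co <- haar_expand(b, t, haar_eval(b, 2, t))
  expect_equal(co[2], 1, tolerance = 1e-9)
  expect_lt(max(abs(co[-2])), 1e-9)
  # zero and constant functions
  expect_equal(haar_expand(b, t, rep(0, 400)), rep(0, 8))
  cc <- haar_expand(b, t, rep(3.5, 400))
  expect_equal(cc[1], 3.5)
  expect_lt(max(abs(cc[-1])), 1e-12)
  # random piecewise-constant at the dyadic resolution: exact
  set.seed(7)
  lv <- runif(8, -2, 2)
  y <- lv[pmin(floor(t / b$dx) + 1, 8)]
  co2 <- haar_expand(b, t, y)
  expect_equal(haar_reconstruct(b, co2, t), y, tolerance = 1e-9)
  expect_error(haar_expand(b, numeric(0), numeric(0)), "non-empty")
})

test_that("network forward pass follows the wavelet-activation equations", {
  m <- wnn_init(1, 1, seed = 1)
  m$W_in <- matrix(1, 1, 1); m$b_in <- 0; m$a <- 1; m$b <- 0; m$W_out <- 0.5
  expect_equal(wnn_forward(m, 0.25), -0.5)   # Psi(0.25) = -1
  expect_equal(wnn_forward(m, 0.75), 0.5)    # Psi(0.75) = +1
  expect_equal(wnn_forward(m, 2), 0)         # outside support

  # zero output weights give zero output for any input
  m0 <- wnn_init(3, 5, seed = 2)
  expect_equal(wnn_forward(m0, matrix(rnorm(15), 5, 3)), rep(0, 5))

  # output linear in the output weights
  mc <- m; mc$W_out <- m$W_out * 3
  expect_equal(wnn_forward(mc, 0.75), 3 * wnn_forward(m, 0.75))

  expect_error(wnn_forward(m, c(1, 2)), "dimension")
})

test_that("forward output is piecewise constant in the input", {
  set.seed(8)
  X <- matrix(runif(40, -1, 1), 20, 2)
  m <- wnn_init(2, 4, seed = 3, X = X)
  m$W_out <- runif(4, -1, 1)
  y0 <- wnn_forward(m, X)
  y1 <- wnn_forward(m, X + 1e-9)  # perturbation within activation cells
  expect_identical(y0, y1)
})

test_that("sum-of-squares loss matches the definition", {
  expect_equal(sse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(sse_loss(c(1, 0), c(0.5, 0.5)), 0.5)
  r <- 0.3; cc <- 0.2
  expect_equal(sse_loss(c(r + cc), c(0)) - sse_loss(c(r), c(0)),
               (r + cc)^2 - r^2)
  expect_equal(sse_loss(c(1, 0), c(0.5, 0.5), mean = TRUE), 0.25)
  expect_error(sse_loss(1:3, 1:2), "equal length")
})

test_that("LM training converges on exactly-fit and separable data", {
  # data already fit exactly: zero-iteration convergence, history [0]
  m <- wnn_init(1, 1, seed = 1)
  m$W_in <- matrix(1, 1, 1); m$b_in <- 0; m$a <- 1; m$b <- 0; m$W_out <- 1
  X <- matrix(c(0.25, 0.75), 2, 1)
  y <- wnn_forward(m, X)
  tr <- lm_train(m, X, y)
  expect_identical(attr(tr, "epochs"), 0L)
  expect_equal(attr(tr, "history"), 0)

  # two separated clusters: perfect training accuracy at threshold 0.5
  set.seed(42)
  n <- 30
  X2 <- rbind(cbind(rnorm(n, 0, 1), rnorm(n, 0, 1)),
              cbind(rnorm(n, 4, 1), rnorm(n, 4, 1)))
  y2 <- c(rep(0, n), rep(1, n))
  net <- lm_train(wnn_init(2, 6, seed = 7, X = X2), X2, y2, max_epochs = 60)
  expect_equal(mean((predict(net, X2)$score >= 0.5) == (y2 == 1)), 1)

  # accepted steps never increase the loss
  h <- attr(net, "history")
  expect_true(all(diff(h) <= 1e-12))

  # determinism: same seed and data give identical parameters
  net2 <- lm_train(wnn_init(2, 6, seed = 7, X = X2), X2, y2, max_epochs = 60)
  expect_identical(net$W_in, net2$W_in)
  expect_identical(net$W_out, net2$W_out)
  expect_identical(attr(net, "history"), attr(net2, "history"))
})

test_that("prediction thresholds at 0.5 with ties to malignant", {
  m <- wnn_init(1, 1, seed = 1, X = matrix(c(0, 1), 2, 1))
  m$W_out <- 1; m$trained <- TRUE
  p <- predict(m, matrix(c(0.2, 0.9), 2, 1))
  expect_identical(nrow(p), 2L)
  # exact threshold and far-negative scores
  fake <- data.frame(score = c(0.5, -3))
  expect_identical(ifelse(fake$score >= 0.5, "malignant", "benign"),
                   c("malignant", "benign"))
  # batch prediction equals per-row prediction
  single <- vapply(1:2, function(i) predict(m, matrix(c(0.2, 0.9)[i], 1, 1))$score,
                   numeric(1))
  expect_equal(p$score, single)
  m$trained <- FALSE
  expect_warning(predict(m, matrix(0.2, 1, 1)), "untrained")
})

test_that("model serialization roundtrips through JSON", {
  X <- matrix(runif(20), 10, 2)
  m <- lm_train(wnn_init(2, 3, seed = 5, X = X), X, runif(10), max_epochs = 5)
  path <- tempfile(fileext = ".json")
  wnn_save(m, path)
  m2 <- wnn_load(path)
  expect_equal(m$W_in, m2$W_in)
  expect_equal(m$W_out, m2$W_out)
  expect_equal(wnn_forward(m, X), wnn_forward(m2, X))
})
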