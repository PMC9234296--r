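#' Haar wavelet family on an interval
#'
#' Builds the `2M`-member Haar family on `[A, B]`: the scaling function
#' `h_1` (1 on `[A, B]`) and, for `i = 2..2M`, the wavelet at level `j`
#' (`m = 2^j`) and translation `k` (`i = m + k + 1`), with breakpoints
#' \deqn{\xi_1 = A + 2k\mu\Delta x,\quad \xi_2 = A + (2k+1)\mu\Delta x,
#' \quad \xi_3 = A + (2k+2)\mu\Delta x}
#' where `mu = M/m` and `Delta x = (B - A)/(2M)`. The two half-supports
#' have equal width, supports at each level tile `[A, B]`, and the
#' family is orthogonal under the `L2` inner product.
#'
#' @param M resolution parameter, a power of two (the family has `2M`
#'   members).
#' @param A,B domain endpoints, `A < B`. Defaults 0 and 1.
#' @return object of class `haar_basis` with the per-index table
#'   (`i, j, k, m, xi1, xi2, xi3`).
#' @export
haar_basis <- function(M, A = 0, B = 1) {
  M <- as.integer(M)
  if (M < 1L || bitwAnd(M, M - 1L) != 0L) {
    stop("`M` must be a positive power of two", call. = FALSE)
  }
  if (!(A < B)) stop("need A < B", call. = FALSE)
  dx <- (B - A) / (2 * M)
  idx <- if (M > 1L) 2:(2L * M) else 2L
  tab <- do.call(rbind, lapply(idx, function(i) {
    m <- 2^floor(log2(i - 1))
    k <- i - 1 - m
    mu <- M / m
    data.frame(i = i, j = log2(m), k = k, m = m,
               xi1 = A + 2 * k * mu * dx,
               xi2 = A + (2 * k + 1) * mu * dx,
               xi3 = A + (2 * k + 2) * mu * dx)
  }))
  structure(list(A = A, B = B, M = M, dx = dx, table = tab),
            class = "haar_basis")
}

#' Evaluate one member of the Haar family
#'
#' `i = 1` is the scaling function: 1 on `[A, B]`, 0 outside. For
#' `i >= 2` the wavelet is -1 on `[xi1, xi2)`, +1 on `[xi2, xi3)` and 0
#' elsewhere (the family's sign convention puts the negative half
#' first).
#'
#' @param basis a [haar_basis()].
#' @param i member index in `1..2M`.
#' @param t numeric vector of evaluation points.
#' @return numeric vector of values in `{-1, 0, 1}`.
#' @export
haar_eval <- function(basis, i, t) {
  stopifnot(inherits(basis, "haar_basis"))
  i <- as.integer(i)
  if (i < 1L || i > 2L * basis$M) stop("index `i` out of range", call. = FALSE)
  if (i == 1L) {
    return(as.numeric(t >= basis$A & t <= basis$B))
  }
  row <- basis$table[basis$table$i == i, ]
  out <- numeric(length(t))
  out[t >= row$xi1 & t < row$xi2] <- -1
  out[t >= row$xi2 & t < row$xi3] <- 1
  out
}

#' Expand sampled data in the Haar family
#'
#' Computes expansion coefficients `a_i = <y, h_i> / <h_i, h_i>` by
#' exact cell quadrature: samples are averaged over the `2M` dyadic
#' cells of width `Delta x`, on which every family member is constant.
#' A function that is piecewise constant on the dyadic grid is
#' reconstructed exactly by `sum_i a_i h_i`.
#'
#' @param basis a [haar_basis()].
#' @param t,y sample locations in `[A, B]` and values; every dyadic cell
#'   must contain at least one sample.
#' @return numeric coefficient vector of length `2M` (index `i`).
#' @export
haar_expand <- function(basis, t, y) {
  stopifnot(inherits(basis, "haar_basis"))
  if (length(t) == 0 || length(t) != length(y)) {
    stop("`t` and `y` must be non-empty and of equal length", call. = FALSE)
  }
  n_cells <- 2L * basis$M
  cell <- pmin(pmax(floor((t - basis$A) / basis$dx) + 1, 1), n_cells)
  means <- tapply(y, factor(cell, levels = seq_len(n_cells)), mean)
  if (anyNA(means)) stop("every dyadic cell needs at least one sample", call. = FALSE)
  means <- as.numeric(means)
  mid <- basis$A + (seq_len(n_cells) - 0.5) * basis$dx
  coef <- numeric(n_cells)
  for (i in seq_len(n_cells)) {
    h <- haar_eval(basis, i, mid)           # constant per cell
    num <- sum(h * means) * basis$dx        # <y, h_i>
    den <- sum(h * h) * basis$dx            # <h_i, h_i>
    coef[i] <- num / den
  }
  coef
}

#' Reconstruct from Haar coefficients
#'
#' @param basis a [haar_basis()].
#' @param coef coefficients from [haar_expand()].
#' @param t evaluation points.
#' @return numeric vector `sum_i coef[i] h_i(t)`.
#' @export
haar_reconstruct <- function(basis, coef, t) {
  stopifnot(inherits(basis, "haar_basis"), length(coef) == 2L * basis$M)
  out <- numeric(length(t))
  for (i in seq_along(coef)) {
    if (coef[i] != 0) out <- out + coef[i] * haar_eval(basis, i, t)
  }
  out
}

# Mother Haar on [0, 1): -1 on [0, 1/2), +1 on [1/2, 1), 0 elsewhere.
haar_mother <- function(u) {
  out <- numeric(length(u))
  out[u >= 0 & u < 0.5] <- -1
  out[u >= 0.5 & u < 1] <- 1
  dim(out) <- dim(u)
  out
}

# Derivative of the piecewise-linear smoothed Haar used as the LM
# gradient surrogate: linear ramps of width `eps` centered on the
# breakpoints 0 (0 -> -1), 1/2 (-1 -> +1) and 1 (+1 -> 0).
haar_mother_grad <- function(u, eps) {
  g <- numeric(length(u))
  g[abs(u) < eps / 2] <- -1 / eps
  g[abs(u - 0.5) < eps / 2] <- 2 / eps
  g[abs(u - 1) < eps / 2] <- -1 / eps
  dim(g) <- dim(u)
  g
}

# Smoothed Haar value (for the optional fully-smooth training mode).
haar_mother_smooth <- function(u, eps) {
  ramp <- function(x) pmin(pmax(x, 0), 1)
  -ramp((u + eps / 2) / eps) + 2 * ramp((u - 0.5 + eps / 2) / eps) -
    ramp((u - 1 + eps / 2) / eps)
}

#' Initialize a wavelet neural network
#'
#' Three-layer network: `F` inputs, `Z` hidden wavelet neurons, one
#' linear output. Input weights and biases are drawn from a seeded
#' uniform(-s, s) with `s = init_scale` (default `1/sqrt(F)`); output
#' weights start at zero, so the first Levenberg-Marquardt step is an
#' exact linear solve on the hidden features. Wavelet scales `a_j`
#' start at the width of the observed pre-activation range of a forward
#' pre-pass (so each neuron's support covers the data), and the
#' translations `b_j` are placed so the wavelet sign flips (`u = 0.5`)
#' are spread uniformly over that range: each hidden unit starts as a
#' soft threshold at a distinct pre-activation level. A unit-scale
#' start (`a_j = 1`) leaves almost every sample on a flat piece of the
#' activation, where both the exact and the surrogate gradient vanish
#' and training stalls.
#'
#' @param F input feature count.
#' @param Z hidden-neuron count.
#' @param seed RNG seed for the weight draw.
#' @param init_scale input-weight scale; default `1/sqrt(F)`.
#' @param X optional training inputs (matrix, rows = samples) used to
#'   spread the translations.
#' @return object of class `wnn`: list with `W_in` (Z x F), `b_in`,
#'   `a`, `b`, `W_out` (all length Z), `F`, `Z`, `trained`.
#' @export
wnn_init <- function(F, Z, seed = 1L, init_scale = NULL, X = NULL) {
  F <- as.integer(F); Z <- as.integer(Z)
  stopifnot(F >= 1, Z >= 1)
  if (is.null(init_scale)) init_scale <- 1 / sqrt(F)
  with_seed(seed, {
    W_in <- matrix(runif(Z * F, -init_scale, init_scale), Z, F)
    b_in <- runif(Z, -init_scale, init_scale)
    rng <- if (!is.null(X)) {
      net <- as.matrix(X) %*% t(W_in) + matrix(b_in, nrow(X), Z, byrow = TRUE)
      range(net)
    } else c(-1, 1)
    if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
    a <- rep(diff(rng), Z)
    splits <- seq(rng[1], rng[2], length.out = Z + 2)[2:(Z + 1)]
    b <- splits - a / 2
    structure(list(W_in = W_in, b_in = b_in, a = a, b = b,
                   W_out = rep(0, Z), F = F, Z = Z, trained = FALSE),
              class = "wnn")
  })
}

#' Wavelet network forward pass
#'
#' Pre-activations `net_j = sum_i x_i W_ij + b_j^{in}`, hidden
#' activations `Psi((net_j - b_j)/a_j)` with `Psi` the mother Haar (-1
#' on `[0, 1/2)`, +1 on `[1/2, 1)`, 0 elsewhere), and a linear output
#' `y = sum_j W_jk Psi_j`. The output is piecewise constant in the
#' input.
#'
#' @param model a `wnn` object.
#' @param X numeric matrix (rows = samples, `F` columns) or a single
#'   feature vector.
#' @return numeric vector of output scores, one per row.
#' @export
wnn_forward <- function(model, X) {
  stopifnot(inherits(model, "wnn"))
  if (is.null(dim(X))) X <- matrix(X, nrow = 1)
  X <- as.matrix(X)
  if (ncol(X) != model$F) stop("input dimension mismatch", call. = FALSE)
  net <- X %*% t(model$W_in) + matrix(model$b_in, nrow(X), model$Z, byrow = TRUE)
  u <- sweep(sweep(net, 2, model$b, `-`), 2, model$a, `/`)
  as.vector(haar_mother(u) %*% model$W_out)
}

#' Sum-of-squares loss
#'
#' `sum_p (t_p - y_p)^2`, the network's training fitness. Non-negative
#' and zero exactly at a perfect fit. `mean = TRUE` gives the
#' mean-normalized variant for reporting.
#'
#' @param targets,outputs numeric vectors of equal length.
#' @param mean divide by the sample count. Default `FALSE`.
#' @return scalar loss.
#' @export
sse_loss <- function(targets, outputs, mean = FALSE) {
  if (length(targets) != length(outputs)) {
    stop("`targets` and `outputs` must have equal length", call. = FALSE)
  }
  s <- sum((targets - outputs)^2)
  if (mean) s / length(targets) else s
}

# --- parameter packing -------------------------------------------------

wnn_pack <- function(m, train_ab) {
  if (train_ab) c(as.vector(m$W_in), m$b_in, m$W_out, m$a, m$b)
  else c(as.vector(m$W_in), m$b_in, m$W_out)
}

wnn_unpack <- function(m, theta, train_ab) {
  Z <- m$Z; F <- m$F
  m$W_in <- matrix(theta[seq_len(Z * F)], Z, F)
  off <- Z * F
  m$b_in <- theta[off + seq_len(Z)]; off <- off + Z
  m$W_out <- theta[off + seq_len(Z)]; off <- off + Z
  if (train_ab) {
    m$a <- pmax(theta[off + seq_len(Z)], 1e-3); off <- off + Z
    m$b <- theta[off + seq_len(Z)]
  }
  m
}

# Jacobian of outputs w.r.t. parameters. The forward pass is exact Haar;
# gradients through the activation use the smoothed-Haar surrogate of
# width eps (the exact activation has zero derivative a.e.).
wnn_jacobian <- function(m, X, eps, train_ab, smooth_forward = FALSE) {
  n <- nrow(X); Z <- m$Z; F <- m$F
  net <- X %*% t(m$W_in) + matrix(m$b_in, n, Z, byrow = TRUE)
  u <- sweep(sweep(net, 2, m$b, `-`), 2, m$a, `/`)
  h <- if (smooth_forward) haar_mother_smooth(u, eps) else haar_mother(u)
  g <- haar_mother_grad(u, eps)                      # n x Z
  wg <- sweep(g, 2, m$W_out / m$a, `*`)              # dY/dnet_j
  J <- matrix(0, n, length(wnn_pack(m, train_ab)))
  for (j in seq_len(Z)) {
    cols <- (j - 1) + seq(1, Z * F, by = Z)          # W_in[j, ] columns
    J[, cols] <- wg[, j] * X
  }
  off <- Z * F
  J[, off + seq_len(Z)] <- wg                        # b_in
  J[, off + Z + seq_len(Z)] <- h                     # W_out
  if (train_ab) {
    ga <- -sweep(g * u, 2, m$W_out / m$a, `*`)       # d/da_j
    gb <- -wg                                        # d/db_j
    J[, off + 2 * Z + seq_len(Z)] <- ga
    J[, off + 3 * Z + seq_len(Z)] <- gb
  }
  list(J = J, y = as.vector(h %*% m$W_out))
}

#' Levenberg-Marquardt training of a wavelet network
#'
#' Damped Gauss-Newton steps on all trainable parameters. Loss is the
#' sum of squares evaluated with the exact Haar forward pass; Jacobians
#' use a piecewise-linear smoothed Haar of transition width `epsilon`
#' because the exact activation has zero derivative almost everywhere.
#' Steps are accepted only if they strictly decrease the loss (damping
#' is increased and the step retried otherwise), so the recorded loss
#' history is monotone non-increasing. Training is deterministic: all
#' randomness lives in [wnn_init()].
#'
#' @param model a `wnn` object (typically from [wnn_init()]).
#' @param X training inputs (rows = samples).
#' @param targets numeric target vector (benign 0 / malignant 1).
#' @param max_epochs accepted-step budget. Default 50.
#' @param lambda0 initial LM damping. Default 1e-2.
#' @param lambda_up,lambda_down damping multipliers on rejected /
#'   accepted steps. Defaults 10 and 0.2.
#' @param epsilon gradient-surrogate transition width. Default 0.1.
#' @param tol early-stop loss tolerance; an initial loss at or below it
#'   returns immediately with a single-entry history. Default 1e-10.
#' @param train_ab train the wavelet scales/translations `a_j`, `b_j`
#'   (`TRUE`, default) or freeze them.
#' @param smooth_forward use the smoothed Haar in the forward pass as
#'   well (fully-smooth training mode). Default `FALSE`.
#' @return the trained `wnn` with attributes `history` (accepted losses,
#'   starting at the initial loss) and `epochs`.
#' @export
lm_train <- function(model, X, targets, max_epochs = 50L, lambda0 = 1e-2,
                     lambda_up = 10, lambda_down = 0.2, epsilon = 0.1,
                     tol = 1e-10, train_ab = TRUE, smooth_forward = FALSE) {
  stopifnot(inherits(model, "wnn"))
  X <- as.matrix(X)
  if (nrow(X) < 1) stop("need at least one training sample", call. = FALSE)
  if (nrow(X) != length(targets)) stop("X/targets length mismatch", call. = FALSE)
  fwd <- function(m) {
    if (smooth_forward) {
      net <- X %*% t(m$W_in) + matrix(m$b_in, nrow(X), m$Z, byrow = TRUE)
      u <- sweep(sweep(net, 2, m$b, `-`), 2, m$a, `/`)
      as.vector(haar_mother_smooth(u, epsilon) %*% m$W_out)
    } else wnn_forward(m, X)
  }
  loss <- sse_loss(targets, fwd(model))
  history <- loss
  if (loss <= tol) {
    model$trained <- TRUE
    attr(model, "history") <- history
    attr(model, "epochs") <- 0L
    return(model)
  }
  lambda <- lambda0
  theta <- wnn_pack(model, train_ab)
  epochs <- 0L
  while (epochs < max_epochs) {
    jac <- wnn_jacobian(model, X, epsilon, train_ab, smooth_forward)
    r <- jac$y - targets
    Jt <- crossprod(jac$J)
    g <- crossprod(jac$J, r)
    accepted <- FALSE
    for (try in 1:25) {
      step <- tryCatch(
        solve(Jt + lambda * diag(nrow(Jt)), -g),
        error = function(e) NULL)
      if (!is.null(step)) {
        cand <- wnn_unpack(model, theta + as.vector(step), train_ab)
        new_loss <- sse_loss(targets, fwd(cand))
        if (is.finite(new_loss) && new_loss < loss) {
          model <- cand
          theta <- wnn_pack(model, train_ab)
          loss <- new_loss
          lambda <- max(lambda * lambda_down, 1e-12)
          accepted <- TRUE
          break
        }
      }
      lambda <- lambda * lambda_up
      if (lambda > 1e12) break
    }
    if (!accepted) break  # no descent direction left at any damping
    epochs <- epochs + 1L
    history <- c(history, loss)
    if (loss <= tol) break
  }
  model$trained <- TRUE
  attr(model, "history") <- history
  attr(model, "epochs") <- epochs
  model
}

#' Predict lesion class from a trained network
#'
#' The score is the raw forward output; the class is malignant when the
#' score is at least `threshold` (ties go to malignant).
#'
#' @param object a `wnn` object.
#' @param newdata feature matrix or single vector.
#' @param threshold decision threshold. Default 0.5.
#' @param ... unused.
#' @return data.frame with `score` and `class`
#'   (`"benign"`/`"malignant"`).
#' @export
predict.wnn <- function(object, newdata, threshold = 0.5, ...) {
  if (!isTRUE(object$trained)) {
    warning("predicting with an untrained network")
  }
  score <- wnn_forward(object, newdata)
  data.frame(score = score,
             class = ifelse(score >= threshold, "malignant", "benign"),
             stringsAsFactors = FALSE)
}

#' @export
print.wnn <- function(x, ...) {
  cat(sprintf("wnn: %d-%d-1 Haar wavelet network (%s)\n", x$F, x$Z,
              if (isTRUE(x$trained)) "trained" else "untrained"))
  invisible(x)
}

#' Serialize a wavelet network to JSON
#'
#' @param model a `wnn` object.
#' @param path file path.
#' @export
wnn_save <- function(model, path) {
  stopifnot(inherits(model, "wnn"))
  obj <- unclass(model)
  obj$W_in <- as.vector(obj$W_in)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a wavelet network from JSON
#'
#' @param path file written by [wnn_save()].
#' @return a `wnn` object.
#' @export
wnn_load <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  obj$W_in <- matrix(obj$W_in, obj$Z, obj$F)
  structure(obj[c("W_in", "b_in", "a", "b", "W_out", "F", "Z", "trained")],
            class = "wnn")
}
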