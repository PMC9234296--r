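# Position update of the grey wolf encircling equations. For each wolf
# u, dimension v and leader l in {alpha, beta, delta}:
#   E = 2 r2,  D = |E * X_l - X_u|,  C = 2 a r1 - a,  X_l' = X_l - C D,
# and the new position is the average (X1 + X2 + X3)/3. `r1`/`r2` may be
# supplied (S x d x 3 arrays) for deterministic hand-traced tests;
# by default they are redrawn per wolf, dimension and leader.
gwo_position_update <- function(X, leaders, a, r1 = NULL, r2 = NULL) {
  S <- nrow(X); d <- ncol(X)
  if (is.null(r1)) r1 <- array(runif(S * d * 3), c(S, d, 3))
  if (is.null(r2)) r2 <- array(runif(S * d * 3), c(S, d, 3))
  newX <- matrix(0, S, d)
  for (l in 1:3) {
    Xl <- matrix(leaders[l, ], S, d, byrow = TRUE)
    E <- 2 * r2[, , l, drop = TRUE]
    C <- 2 * a * r1[, , l, drop = TRUE] - a
    dim(E) <- c(S, d); dim(C) <- c(S, d)
    D <- abs(E * Xl - X)
    newX <- newX + (Xl - C * D)
  }
  newX / 3
}

#' One grey wolf optimization step
#'
#' Moves every wolf by the encircling update steered by the three
#' current leaders (alpha, beta, delta), clips positions to the bounds,
#' re-evaluates fitness, and updates the leaders elitistically (a leader
#' is replaced only by a strictly better wolf, so the alpha fitness is
#' monotone non-increasing). Non-finite fitness values are treated as
#' `+Inf` so such wolves never lead.
#'
#' @param state list with `X` (S x d positions), `fitness`, `leaders`
#'   (3 x d), `leader_fitness` (length 3).
#' @param fn scalar fitness function of a position vector (minimized).
#' @param a encircling schedule value in `[0, 2]`.
#' @param lower,upper per-dimension bounds.
#' @return updated state.
#' @export
gwo_step <- function(state, fn, a, lower, upper) {
  X <- gwo_position_update(state$X, state$leaders, a)
  X <- sweep(sweep(X, 2, upper, pmin), 2, lower, pmax)
  fitness <- apply(X, 1, function(p) {
    f <- tryCatch(fn(p), error = function(e) Inf)
    if (!is.finite(f)) Inf else f
  })
  state$X <- X
  state$fitness <- fitness
  for (u in order(fitness)) {
    f <- fitness[u]
    if (f < state$leader_fitness[1]) {
      state$leaders <- rbind(X[u, ], state$leaders[1:2, , drop = FALSE])
      state$leader_fitness <- c(f, state$leader_fitness[1:2])
    } else if (f < state$leader_fitness[2]) {
      state$leaders <- rbind(state$leaders[1, , drop = FALSE], X[u, ],
                             state$leaders[2, , drop = FALSE])
      state$leader_fitness <- c(state$leader_fitness[1], f,
                                state$leader_fitness[2])
    } else if (f < state$leader_fitness[3]) {
      state$leaders[3, ] <- X[u, ]
      state$leader_fitness[3] <- f
    }
  }
  state
}

#' Grey wolf optimization
#'
#' Population metaheuristic in which the three best agents (alpha, beta,
#' delta) steer the pack. The encircling coefficient schedule decays
#' linearly `a = 2 (1 - t / I_max)`, exploratory early and exploitative
#' late. Deterministic given `seed`; returns the alpha wolf.
#'
#' @param fn scalar fitness function (minimized).
#' @param lower,upper per-dimension bounds (finite, `lower < upper`).
#' @param S population size, at least 3. Default 15.
#' @param I_max iteration budget; 0 returns the best of the seeded
#'   initial population. Default 30.
#' @param seed RNG seed.
#' @return object of class `gwo_result`: `par` (alpha position), `value`
#'   (alpha fitness), `history` (best fitness after initialization and
#'   after each iteration, monotone non-increasing), `evaluations`.
#' @export
gwo_optimize <- function(fn, lower, upper, S = 15L, I_max = 30L, seed = 1L) {
  S <- as.integer(S); I_max <- as.integer(I_max)
  if (S < 3L) stop("`S` must be at least 3 (alpha/beta/delta)", call. = FALSE)
  if (I_max < 0L) stop("`I_max` must be >= 0", call. = FALSE)
  d <- length(lower)
  if (length(upper) != d || any(!is.finite(lower)) || any(!is.finite(upper)) ||
      any(lower >= upper)) {
    stop("bounds must be finite with lower < upper", call. = FALSE)
  }
  with_seed(seed, {
    X <- matrix(runif(S * d), S, d)
    X <- sweep(sweep(X, 2, upper - lower, `*`), 2, lower, `+`)
    fitness <- apply(X, 1, function(p) {
      f <- tryCatch(fn(p), error = function(e) Inf)
      if (!is.finite(f)) Inf else f
    })
    ord <- order(fitness)[1:3]
    state <- list(X = X, fitness = fitness,
                  leaders = X[ord, , drop = FALSE],
                  leader_fitness = fitness[ord])
    history <- state$leader_fitness[1]
    t <- 0L
    while (t < I_max) {
      t <- t + 1L
      a <- 2 * (1 - t / I_max)
      state <- gwo_step(state, fn, a, lower, upper)
      history <- c(history, state$leader_fitness[1])
    }
    structure(list(par = as.vector(state$leaders[1, ]),
                   value = state$leader_fitness[1],
                   history = history,
                   evaluations = S * (I_max + 1L)),
              class = "gwo_result")
  })
}

#' @export
print.gwo_result <- function(x, ...) {
  cat(sprintf("gwo_result: best fitness %.6g after %d evaluations\n",
              x$value, x$evaluations))
  invisible(x)
}

#' Hyperparameter search space for the wavelet network
#'
#' Three dimensions: hidden-neuron count `Z` (integer, rounded on
#' decode), initial LM damping (log10 scale) and weight-initialization
#' scale (log10 scale).
#'
#' @param Z_range integer bounds on the hidden-neuron count. Default
#'   `c(2, 30)`.
#' @param log_lambda_range log10 bounds on the initial LM damping.
#'   Default `c(-4, 1)`.
#' @param log_scale_range log10 bounds on the weight-init scale.
#'   Default `c(-2, 0.5)`.
#' @return list with `lower`, `upper`, and `decode(position)` returning
#'   `list(Z, lambda0, init_scale)`.
#' @export
hyperparam_space <- function(Z_range = c(2L, 30L),
                             log_lambda_range = c(-4, 1),
                             log_scale_range = c(-2, 0.5)) {
  lower <- c(Z_range[1], log_lambda_range[1], log_scale_range[1])
  upper <- c(Z_range[2], log_lambda_range[2], log_scale_range[2])
  decode <- function(p) {
    Z <- as.integer(round(p[1]))
    if (Z < Z_range[1] || Z > Z_range[2]) stop("decoded Z out of bounds")
    list(Z = Z, lambda0 = 10^p[2], init_scale = 10^p[3])
  }
  list(lower = lower, upper = upper, decode = decode)
}

#' Tune wavelet-network hyperparameters with grey wolf optimization
#'
#' Splits the training table into tuning-train and tuning-validation
#' subsets (stratified, seeded) before any fitness evaluation. A
#' candidate's fitness is the sum-of-squares validation loss after a
#' budgeted Levenberg-Marquardt training from the decoded
#' hyperparameters. The final model is retrained on the full training
#' table with the best candidate.
#'
#' @param X numeric feature matrix (training rows only, e.g. PCA
#'   scores).
#' @param labels character/factor vector (`"benign"`/`"malignant"`).
#' @param space a [hyperparam_space()].
#' @param S,I_max GWO population and iteration budget. Defaults 15, 30.
#' @param seed master seed (drives split, GWO and weight draws).
#' @param tune_epochs LM epoch budget per fitness evaluation.
#'   Default 15.
#' @param final_epochs LM epochs for the final retrain. Default 60.
#' @return list with `hyperparams` (decoded best), `model` (trained
#'   `wnn`), `report` (data.frame: one row per fitness evaluation),
#'   `gwo` (the `gwo_result`), and `tune_split` (the internal
#'   tuning-train/validation `split_plan`; its `test_idx` rows are the
#'   validation subset every fitness value was computed on).
#' @export
tune_wnn <- function(X, labels, space = hyperparam_space(), S = 15L,
                     I_max = 30L, seed = 1L, tune_epochs = 15L,
                     final_epochs = 60L) {
  X <- as.matrix(X)
  y <- as_binary_labels(labels)
  plan <- split_and_cv(labels, seed = seed, train_frac = 0.7, folds = 2L,
                       quiet = TRUE)
  it_r <- plan$train_idx; iv <- plan$test_idx
  report <- new.env(parent = emptyenv())
  report$rows <- list()
  fitness <- function(p) {
    hp <- tryCatch(space$decode(p), error = function(e) NULL)
    if (is.null(hp)) return(Inf)
    net <- wnn_init(ncol(X), hp$Z, seed = seed + 1L,
                    init_scale = hp$init_scale, X = X[it_r, , drop = FALSE])
    net <- lm_train(net, X[it_r, , drop = FALSE], y[it_r],
                    max_epochs = tune_epochs, lambda0 = hp$lambda0)
    f <- sse_loss(y[iv], wnn_forward(net, X[iv, , drop = FALSE]))
    report$rows[[length(report$rows) + 1L]] <-
      data.frame(Z = hp$Z, lambda0 = hp$lambda0, init_scale = hp$init_scale,
                 fitness = f)
    f
  }
  gw <- gwo_optimize(fitness, space$lower, space$upper, S = S, I_max = I_max,
                     seed = seed + 2L)
  best <- space$decode(gw$par)
  final <- wnn_init(ncol(X), best$Z, seed = seed + 1L,
                    init_scale = best$init_scale, X = X)
  final <- lm_train(final, X, y, max_epochs = final_epochs,
                    lambda0 = best$lambda0)
  list(hyperparams = best, model = final,
       report = do.call(rbind, report$rows), gwo = gw, tune_split = plan)
}
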