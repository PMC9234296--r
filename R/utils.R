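# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# RNG state. All stochastic entry points route their seeds through here.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
      stop("`seed` must be a single finite number", call. = FALSE)
    }
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(code)
}

check_image <- function(image, min_dim = 1L, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(image) < min_dim || ncol(image) < min_dim) {
    stop(sprintf("`%s` must be at least %dx%d", arg, min_dim, min_dim),
         call. = FALSE)
  }
  if (!all(is.finite(image))) {
    stop(sprintf("`%s` contains non-finite pixel values", arg), call. = FALSE)
  }
  invisible(image)
}

check_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask)) stop(sprintf("`%s` must be a matrix", arg), call. = FALSE)
  v <- unique(as.vector(mask))
  if (!all(v %in% c(0, 1))) {
    stop(sprintf("`%s` must be binary (0/1)", arg), call. = FALSE)
  }
  invisible(mask)
}

#' Dice overlap between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`; returns 1 when both masks are empty.
#'
#' @param a,b binary (0/1) matrices of identical shape.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check_mask(a, "a"); check_mask(b, "b")
  if (!all(dim(a) == dim(b))) stop("mask shapes differ", call. = FALSE)
  sa <- sum(a); sb <- sum(b)
  if (sa + sb == 0) return(1)
  2 * sum(a * b) / (sa + sb)
}

# Replicate-pad a matrix by `k` pixels on every side.
pad_replicate <- function(img, k) {
  h <- nrow(img); w <- ncol(img)
  img[c(rep(1L, k), seq_len(h), rep(h, k)),
      c(rep(1L, k), seq_len(w), rep(w, k)), drop = FALSE]
}
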