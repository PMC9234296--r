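#' Specification of a synthetic speckled-ultrasound phantom
#'
#' Describes one synthetic B-mode-like image: a hypoechoic (darker)
#' lesion on a brighter background, multiplied by gamma-distributed
#' speckle. Benign lesions have a smooth elliptical boundary; malignant
#' lesions have an irregular, spiculated boundary
#' `r(theta) = r0 (1 + A sin(p theta + phi) + jitter)`.
#'
#' @param label `"benign"` or `"malignant"`.
#' @param size image side length in pixels. Default 128.
#' @param background mean background echo level (arbitrary intensity
#'   units). Default 180.
#' @param contrast lesion contrast factor in `(0, 1)`: lesion interior
#'   mean = `background * contrast`. Default 0.5 (hypoechoic).
#' @param axes benign ellipse semi-axes in pixels. Default `c(22, 15)`.
#' @param orientation benign ellipse orientation in radians; `NULL`
#'   draws it from the sample seed.
#' @param base_radius malignant base radius in pixels. Default 18.
#' @param n_spikes malignant spiculation count. Default 9.
#' @param spike_amp malignant spike amplitude as a fraction of
#'   `base_radius`. Default 0.35.
#' @param looks speckle "looks" L: multiplicative noise is
#'   gamma(shape = L, mean = 1), giving a coefficient of variation of
#'   `1/sqrt(L)`. Default 4.
#' @param blur Gaussian blur width (sigma, pixels) applied to the clean
#'   echo map before speckle, emulating the system point-spread
#'   function. Default 1.2.
#' @param seed RNG seed for this sample.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(label = c("benign", "malignant"), size = 128L,
                         background = 180, contrast = 0.5,
                         axes = c(22, 15), orientation = NULL,
                         base_radius = 18, n_spikes = 9L, spike_amp = 0.35,
                         looks = 4, blur = 1.2, seed = 1L) {
  label <- match.arg(label)
  size <- as.integer(size)
  if (size < 32L) stop("`size` must be at least 32", call. = FALSE)
  if (contrast <= 0 || contrast > 1) {
    stop("`contrast` must lie in (0, 1]", call. = FALSE)
  }
  if (looks <= 0) stop("`looks` must be positive", call. = FALSE)
  max_r <- if (label == "benign") max(axes) else base_radius * (1 + spike_amp + 0.15)
  if (max_r + 4 >= size / 2) {
    stop("lesion does not fit inside the frame with margin", call. = FALSE)
  }
  structure(list(label = label, size = size, background = background,
                 contrast = contrast, axes = axes, orientation = orientation,
                 base_radius = base_radius, n_spikes = as.integer(n_spikes),
                 spike_amp = spike_amp, looks = looks, blur = blur,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Separable Gaussian blur via banded row/column operators with
# truncated-and-renormalized kernels at the borders (replicate-like).
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  blur_op <- function(n) {
    r <- max(1L, ceiling(3 * sigma))
    idx <- seq_len(n)
    B <- matrix(0, n, n)
    for (d in -r:r) {
      w <- exp(-d^2 / (2 * sigma^2))
      src <- idx + d
      keep <- src >= 1 & src <= n
      B[cbind(idx[keep], src[keep])] <- B[cbind(idx[keep], src[keep])] + w
    }
    B / rowSums(B)
  }
  Br <- blur_op(nrow(img))
  Bc <- blur_op(ncol(img))
  Br %*% img %*% t(Bc)
}

#' Generate one speckled phantom
#'
#' Builds the clean echo map (background with a hypoechoic lesion whose
#' boundary follows the spec's radial profile), blurs it with a Gaussian
#' point-spread approximation, then multiplies by gamma speckle with
#' shape `looks` and mean 1. Deterministic given `spec$seed`.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_sample`: list with `image` (numeric
#'   matrix), `mask` (0/1 truth matrix), `label`, and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(spec$seed, {
    n <- spec$size
    ctr <- (n + 1) / 2
    rows <- matrix(seq_len(n) - ctr, n, n)
    cols <- matrix(seq_len(n) - ctr, n, n, byrow = TRUE)
    theta <- atan2(rows, cols)
    rr <- sqrt(rows^2 + cols^2)
    orientation <- if (is.null(spec$orientation)) runif(1, 0, pi) else spec$orientation
    if (spec$label == "benign") {
      a <- spec$axes[1]; b <- spec$axes[2]
      rb <- a * b / sqrt((b * cos(theta - orientation))^2 +
                         (a * sin(theta - orientation))^2)
    } else {
      phi0 <- runif(1, 0, 2 * pi)
      # low-order harmonic jitter keeps the boundary irregular but closed
      j_amp <- runif(2, 0.02, 0.08)
      j_ph <- runif(2, 0, 2 * pi)
      jitter <- j_amp[1] * sin(2 * theta + j_ph[1]) +
                j_amp[2] * sin(5 * theta + j_ph[2])
      rb <- spec$base_radius *
        (1 + spec$spike_amp * sin(spec$n_spikes * theta + phi0) + jitter)
      rb <- pmax(rb, 0.25 * spec$base_radius)
    }
    mask <- (rr <= rb) * 1L
    dim(mask) <- c(n, n)
    clean <- spec$background * ifelse(mask == 1L, spec$contrast, 1)
    clean <- gaussian_blur(clean, spec$blur)
    speckle <- matrix(rgamma(n * n, shape = spec$looks, rate = spec$looks), n, n)
    img <- clean * speckle
    structure(list(image = img, mask = mask, label = spec$label, spec = spec),
              class = "phantom_sample")
  })
}

#' Generate a labelled phantom dataset
#'
#' Draws per-sample seeds and jittered lesion geometry from a master
#' seed, then generates `n_benign + n_malignant` phantoms with truth
#' masks. Geometry jitter: ellipse axes and base radius scaled by
#' +/-15%, spike count 7-12, spike amplitude 0.30-0.40, orientation free.
#'
#' @param n_benign,n_malignant sample counts (>= 0).
#' @param seed master seed; per-sample seeds are derived from it.
#' @param size,background,contrast,looks,blur base spec values shared by
#'   all samples, see [phantom_spec()].
#' @return list with `samples` (list of `phantom_sample`) and `manifest`
#'   (data.frame: id, label, seed and geometry parameters).
#' @export
generate_dataset <- function(n_benign, n_malignant, seed = 1L, size = 128L,
                             background = 180, contrast = 0.5, looks = 4,
                             blur = 1.2) {
  stopifnot(n_benign >= 0, n_malignant >= 0)
  n <- n_benign + n_malignant
  labels <- c(rep("benign", n_benign), rep("malignant", n_malignant))
  manifest <- data.frame(id = character(0), label = character(0),
                         seed = integer(0), stringsAsFactors = FALSE)
  if (n == 0) return(list(samples = list(), manifest = manifest))
  specs <- with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      sc <- runif(1, 0.85, 1.15)
      if (labels[i] == "benign") {
        phantom_spec("benign", size = size, background = background,
                     contrast = contrast, axes = c(22, 15) * sc,
                     looks = looks, blur = blur, seed = seeds[i])
      } else {
        phantom_spec("malignant", size = size, background = background,
                     contrast = contrast, base_radius = 18 * sc,
                     n_spikes = sample(7:12, 1),
                     spike_amp = runif(1, 0.30, 0.40),
                     looks = looks, blur = blur, seed = seeds[i])
      }
    })
  })
  samples <- lapply(specs, generate_phantom)
  manifest <- do.call(rbind, lapply(seq_len(n), function(i) {
    sp <- specs[[i]]
    data.frame(id = sprintf("phantom_%03d", i), label = sp$label,
               seed = sp$seed, size = sp$size, contrast = sp$contrast,
               looks = sp$looks,
               geom1 = if (sp$label == "benign") sp$axes[1] else sp$base_radius,
               geom2 = if (sp$label == "benign") sp$axes[2] else sp$spike_amp,
               stringsAsFactors = FALSE)
  }))
  list(samples = samples, manifest = manifest)
}

#' @export
print.phantom_sample <- function(x, ...) {
  cat(sprintf("phantom_sample: %s, %dx%d, lesion %d px, seed %d\n",
              x$label, nrow(x$image), ncol(x$image), sum(x$mask),
              x$spec$seed))
  invisible(x)
}
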