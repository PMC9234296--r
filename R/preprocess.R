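#' Sigmoid contrast enhancement
#'
#' Maps intensities through a logistic curve stretched to the image's own
#' dynamic range:
#' \deqn{H_{enh}(x,y) = (mx - mn) \cdot \frac{1}{1 + e^{(\alpha - H(x,y))/\gamma}} + mn}
#' where `mn`/`mx` are the input's minimum and maximum intensity. The
#' transform is monotone in the input and its output stays inside
#' `[mn, mx]`. On a constant image (`mx == mn`) the scaled term vanishes
#' and the image is returned unchanged at level `mn`.
#'
#' @param image numeric matrix of finite intensities (native scale,
#'   typically 0-255).
#' @param alpha sigmoid center, in intensity units. Default 4.
#' @param gamma sigmoid width, in intensity units, must be positive.
#'   Default 7.
#' @return enhanced image, same dimensions.
#' @export
#' @examples
#' img <- matrix(c(0, 255), 1, 2)
#' sigmoid_enhance(img)  # ~92.0 and ~255
sigmoid_enhance <- function(image, alpha = 4, gamma = 7) {
  check_image(image)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0) {
    stop("`gamma` must be a single positive number", call. = FALSE)
  }
  mn <- min(image); mx <- max(image)
  out <- (mx - mn) / (1 + exp((alpha - image) / gamma)) + mn
  dim(out) <- dim(image)
  out
}

#' Median filter with edge replication
#'
#' Replaces each pixel by the median of its `kernel x kernel`
#' neighborhood. Borders are handled by edge replication so the output
#' shape equals the input shape, and every output value belongs to the
#' input's value set.
#'
#' @param image numeric matrix.
#' @param kernel odd window size, at least 3. Default 3 (small kernels
#'   avoid over-filtering).
#' @return filtered image, same dimensions.
#' @export
median_filter <- function(image, kernel = 3L) {
  check_image(image, min_dim = 3L)
  kernel <- as.integer(kernel)
  if (length(kernel) != 1L || is.na(kernel) || kernel < 3L || kernel %% 2L == 0L) {
    stop("`kernel` must be a single odd integer >= 3", call. = FALSE)
  }
  if (kernel > min(dim(image))) {
    stop("`kernel` larger than the image", call. = FALSE)
  }
  median_filter_cpp(image, kernel)
}

#' Constructive-interference combination
#'
#' Element-wise maximum of the enhanced image and its median-filtered
#' version. Bright speckle corresponds to constructive interference,
#' dark speckle to destructive interference; taking the pixel-wise
#' maximum suppresses the destructive (dark) component while leaving
#' bright structure untouched. The output dominates both inputs at every
#' pixel.
#'
#' @param enhanced,medianed numeric matrices of identical shape.
#' @return element-wise maximum.
#' @export
combine_constructive <- function(enhanced, medianed) {
  check_image(enhanced, arg = "enhanced")
  check_image(medianed, arg = "medianed")
  if (!all(dim(enhanced) == dim(medianed))) {
    stop("`enhanced` and `medianed` must have the same shape", call. = FALSE)
  }
  pmax(enhanced, medianed)
}

#' Perona-Malik anisotropic diffusion
#'
#' Edge-preserving smoothing by iterating the 4-neighbor discretization
#' of the Perona-Malik PDE with exponential conduction
#' `g(d) = exp(-(d/kappa)^2)`. Large gradients (edges) conduct little and
#' are preserved; small gradients (speckle residue) diffuse away. The
#' scheme is extremum-diminishing for `step` in `(0, 0.25]`, so the
#' global intensity range never expands. Zero iterations return the
#' input unchanged.
#'
#' @param image numeric matrix.
#' @param iterations number of diffusion steps (>= 0). Default 15.
#' @param kappa conduction threshold in intensity units, positive.
#'   Gradients well below `kappa` are smoothed, well above preserved.
#'   Default 30.
#' @param step time step, must lie in `(0, 0.25]` for stability.
#'   Default 0.2.
#' @return diffused image, same dimensions.
#' @export
perona_malik_diffuse <- function(image, iterations = 15L, kappa = 30,
                                 step = 0.2) {
  check_image(image, min_dim = 3L)
  iterations <- as.integer(iterations)
  if (is.na(iterations) || iterations < 0L) {
    stop("`iterations` must be >= 0", call. = FALSE)
  }
  if (!is.numeric(kappa) || kappa <= 0) stop("`kappa` must be > 0", call. = FALSE)
  if (!is.numeric(step) || step <= 0 || step > 0.25) {
    stop("`step` must lie in (0, 0.25]", call. = FALSE)
  }
  if (iterations == 0L) return(image)
  h <- nrow(image); w <- ncol(image)
  u <- image
  g <- function(d) exp(-(d / kappa)^2)
  for (it in seq_len(iterations)) {
    # neighbor differences with replicated borders (zero flux at edges)
    dN <- rbind(u[1, , drop = FALSE], u[-h, , drop = FALSE]) - u
    dS <- rbind(u[-1, , drop = FALSE], u[h, , drop = FALSE]) - u
    dW <- cbind(u[, 1, drop = FALSE], u[, -w, drop = FALSE]) - u
    dE <- cbind(u[, -1, drop = FALSE], u[, w, drop = FALSE]) - u
    u <- u + step * (g(dN) * dN + g(dS) * dS + g(dW) * dW + g(dE) * dE)
  }
  u
}

#' Interference-based despeckling with anisotropic diffusion (IDAD)
#'
#' The full despeckling sequence applied to an enhanced ultrasound
#' image: median filter, element-wise maximum with the input
#' (destructive-interference suppression), a second median pass to
#' remove remaining extreme single pixels, then Perona-Malik anisotropic
#' diffusion. The sequence reduces speckle variance in homogeneous
#' regions while preserving lesion edges and boundaries.
#'
#' @param image enhanced numeric matrix.
#' @param kernel odd median window size. Default 3.
#' @param iterations,kappa,step diffusion parameters, see
#'   [perona_malik_diffuse()].
#' @return despeckled image, same dimensions.
#' @export
idad_despeckle <- function(image, kernel = 3L, iterations = 15L, kappa = 30,
                           step = 0.2) {
  check_image(image, min_dim = 3L)
  med <- median_filter(image, kernel)
  hc <- combine_constructive(image, med)
  hc <- median_filter(hc, kernel)
  perona_malik_diffuse(hc, iterations = iterations, kappa = kappa, step = step)
}

#' Full preprocessing stage
#'
#' Sigmoid enhancement followed by IDAD despeckling, the preprocessing
#' applied to every image before segmentation.
#'
#' @inheritParams sigmoid_enhance
#' @inheritParams idad_despeckle
#' @return preprocessed image, same dimensions.
#' @export
preprocess_image <- function(image, alpha = 4, gamma = 7, kernel = 3L,
                             iterations = 15L, kappa = 30, step = 0.2) {
  enh <- sigmoid_enhance(image, alpha = alpha, gamma = gamma)
  idad_despeckle(enh, kernel = kernel, iterations = iterations,
                 kappa = kappa, step = step)
}
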