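#' Deterministic cluster-center initialization
#'
#' Centers are spread evenly over the image's intensity range:
#' `n = max(image) + 1`, `centers = (1..M) * n / (M + 1)`. The
#' initialization is deterministic, so the whole clustering stage is
#' reproducible without random restarts.
#'
#' @param image numeric matrix.
#' @param M number of clusters (>= 1).
#' @return strictly increasing numeric vector of length `M`.
#' @export
#' @examples
#' init_centers(matrix(c(0, 255), 1, 2), 3)  # 64 128 192
init_centers <- function(image, M) {
  check_image(image)
  M <- as.integer(M)
  if (is.na(M) || M < 1L) stop("`M` must be >= 1", call. = FALSE)
  n <- max(image) + 1
  seq_len(M) * n / (M + 1)
}

#' Hybrid k-means / fuzzy c-means intensity clustering
#'
#' Alternates one hard (k-means) sweep and one soft (fuzzy c-means)
#' sweep per outer iteration, from the deterministic [init_centers()]
#' initialization, until the maximum center movement falls below `tol`
#' or `max_iter` outer iterations are reached. The hard sweep assigns
#' each pixel to its nearest center and recomputes centers as cluster
#' means; the soft sweep updates graded memberships
#' `u_ik = 1 / sum_j (d_ik/d_jk)^(1/(fuzzifier-1))` (squared distances)
#' and membership-weighted centers. An emptied cluster is re-seeded to
#' the intensity farthest from the remaining centers (reported via
#' `message()`).
#'
#' @param image despeckled numeric matrix.
#' @param M number of clusters. Default 3 (lesion / parenchyma / bright
#'   tissue).
#' @param fuzzifier FCM exponent, > 1. Default 2.
#' @param max_iter outer iteration cap. Default 100.
#' @param tol center-movement convergence tolerance (intensity units).
#'   Default 1e-3.
#' @return object of class `hybrid_clusters`: list with `centers`
#'   (ascending), `memberships` (pixels x M, rows sum to 1), `labels`
#'   (per-pixel hard assignment, matrix), `objective` (per-iteration
#'   membership-weighted squared distance), `iterations`, `converged`.
#' @export
hybrid_cluster <- function(image, M = 3L, fuzzifier = 2, max_iter = 100L,
                           tol = 1e-3) {
  check_image(image)
  if (fuzzifier <= 1) stop("`fuzzifier` must be > 1", call. = FALSE)
  x <- as.vector(image)
  centers <- init_centers(image, M)
  M <- length(centers)
  exponent <- 1 / (fuzzifier - 1)
  sqd <- function(cent) {
    d <- outer(x, cent, `-`)^2
    pmax(d, .Machine$double.eps)  # avoid 0/0 in the membership ratio
  }
  fcm_memberships <- function(cent) {
    d2 <- sqd(cent)
    inv <- d2^(-exponent)
    inv / rowSums(inv)
  }
  reseed_empty <- function(cent, counts) {
    for (k in which(counts == 0)) {
      gap <- vapply(x, function(v) min(abs(v - cent)), numeric(1))
      cent[k] <- x[which.max(gap)]
      message(sprintf("hybrid_cluster: empty cluster re-seeded to %.3f", cent[k]))
    }
    cent
  }
  objective <- numeric(0)
  converged <- FALSE
  it <- 0L
  u <- fcm_memberships(centers)
  while (it < max_iter) {
    it <- it + 1L
    prev <- centers
    # hard sweep
    d2 <- sqd(centers)
    lab <- max.col(-d2, ties.method = "first")
    counts <- tabulate(lab, nbins = M)
    if (any(counts == 0)) {
      centers <- reseed_empty(centers, counts)
      d2 <- sqd(centers)
      lab <- max.col(-d2, ties.method = "first")
      counts <- tabulate(lab, nbins = M)
    }
    sums <- vapply(seq_len(M), function(k) sum(x[lab == k]), numeric(1))
    centers <- ifelse(counts > 0, sums / pmax(counts, 1L), centers)
    # soft sweep
    u <- fcm_memberships(centers)
    um <- u^fuzzifier
    centers <- colSums(um * x) / colSums(um)
    objective <- c(objective, sum(um * sqd(centers)))
    if (max(abs(centers - prev)) < tol) { converged <- TRUE; break }
  }
  ord <- order(centers)
  u <- fcm_memberships(centers)[, ord, drop = FALSE]
  d2 <- sqd(centers[ord])
  labels <- matrix(max.col(-d2, ties.method = "first"), nrow(image), ncol(image))
  structure(list(centers = centers[ord], memberships = u, labels = labels,
                 objective = objective, iterations = it, converged = converged,
                 M = M, fuzzifier = fuzzifier),
            class = "hybrid_clusters")
}

#' @export
print.hybrid_clusters <- function(x, ...) {
  cat(sprintf("hybrid_clusters: M=%d, %d iterations (%s)\ncenters: %s\n",
              x$M, x$iterations,
              if (x$converged) "converged" else "iteration cap",
              paste(sprintf("%.2f", x$centers), collapse = ", ")))
  invisible(x)
}

#' Binarize the lesion cluster
#'
#' Thresholds the hard cluster labels: the cluster with the lowest
#' intensity center is taken as the lesion (breast lesions are
#' hypoechoic). The raw binary map is cleaned by keeping the largest
#' connected foreground component and filling holes, yielding a white
#' foreground (lesion) on a dark background.
#'
#' @param model a converged [hybrid_cluster()] result.
#' @param image the clustered image (for shape checking).
#' @param lesion_cluster index (in ascending-center order) of the lesion
#'   cluster. Default 1 (lowest center); configurable for inverted
#'   modalities.
#' @return binary 0/1 matrix of the image's shape.
#' @export
binarize_lesion <- function(model, image, lesion_cluster = 1L) {
  stopifnot(inherits(model, "hybrid_clusters"))
  check_image(image)
  if (!all(dim(model$labels) == dim(image))) {
    stop("model/image shape mismatch", call. = FALSE)
  }
  raw <- (model$labels == lesion_cluster) * 1L
  dim(raw) <- dim(image)
  if (sum(raw) == 0) {
    stop("segmentation failure: empty lesion foreground", call. = FALSE)
  }
  lab <- EBImage::bwlabel(raw)
  sizes <- tabulate(as.vector(lab))
  keep <- which.max(sizes)
  mask <- (lab == keep) * 1L
  mask <- as.matrix(EBImage::fillHull(mask))
  storage.mode(mask) <- "integer"
  if (sum(mask) == 0) {
    stop("segmentation failure: empty lesion foreground", call. = FALSE)
  }
  mask
}

# Signed distance field, negative inside the mask.
signed_distance <- function(mask) {
  as.matrix(EBImage::distmap(1L - mask)) - as.matrix(EBImage::distmap(mask))
}

# Mean curvature of the level-set field by central differences.
curvature_field <- function(phi) {
  h <- nrow(phi); w <- ncol(phi)
  shift <- function(m, dr, dc) {
    ri <- pmin(pmax(seq_len(h) + dr, 1L), h)
    ci <- pmin(pmax(seq_len(w) + dc, 1L), w)
    m[ri, ci, drop = FALSE]
  }
  px <- (shift(phi, 0, 1) - shift(phi, 0, -1)) / 2
  py <- (shift(phi, 1, 0) - shift(phi, -1, 0)) / 2
  pxx <- shift(phi, 0, 1) - 2 * phi + shift(phi, 0, -1)
  pyy <- shift(phi, 1, 0) - 2 * phi + shift(phi, -1, 0)
  pxy <- (shift(shift(phi, 1, 0), 0, 1) - shift(shift(phi, 1, 0), 0, -1) -
          shift(shift(phi, -1, 0), 0, 1) + shift(shift(phi, -1, 0), 0, -1)) / 4
  (pxx * py^2 - 2 * px * py * pxy + pyy * px^2) /
    (px^2 + py^2 + .Machine$double.eps)^1.5
}

#' Chan-Vese level-set boundary refinement
#'
#' Refines a binary lesion mask by evolving a signed level-set field
#' (negative inside) under the two-phase Chan-Vese energy: the boundary
#' shrinks or expands so that inside and outside intensities each match
#' their region mean, with a curvature term (weight `mu`) keeping the
#' contour smooth. The field is initialized as the signed distance to
#' the input mask boundary; evolution stops when fewer than `tol` of
#' pixels change sign in an iteration or after `max_iter` iterations.
#' If the contour collapses (empty interior) the pre-refinement mask is
#' returned with a warning.
#'
#' @param mask binary 0/1 matrix, non-empty.
#' @param image the (despeckled) image driving the region terms.
#' @param max_iter iteration budget; 0 returns the mask unchanged.
#'   Default 200.
#' @param mu curvature (smoothness) weight on the normalized intensity
#'   scale. Default 0.2.
#' @param dt time step. Default 0.5.
#' @param tol sign-change fraction below which evolution stops.
#'   Default 1e-3.
#' @return list with `mask` (refined, largest component, holes filled)
#'   and `phi` (final level-set field, negative inside).
#' @export
level_set_refine <- function(mask, image, max_iter = 200L, mu = 0.2,
                             dt = 0.5, tol = 1e-3) {
  check_mask(mask)
  check_image(image)
  if (!all(dim(mask) == dim(image))) stop("mask/image shape mismatch", call. = FALSE)
  if (sum(mask) == 0) stop("`mask` is empty", call. = FALSE)
  max_iter <- as.integer(max_iter)
  phi <- signed_distance(mask)
  if (max_iter == 0L) return(list(mask = mask, phi = phi))
  rng <- range(image)
  I <- if (diff(rng) > 0) (image - rng[1]) / diff(rng) else image * 0
  eps <- 1
  n_px <- length(phi)
  snapshot <- NULL
  for (it in seq_len(max_iter)) {
    if (it %% 20L == 0L) {
      # re-initialize to a signed distance so the delta band tracks the
      # moving contour instead of the initial one; converged when the
      # mask has barely changed over the whole 20-iteration cycle
      cur <- (phi < 0) * 1L
      dim(cur) <- dim(phi)
      if (!is.null(snapshot) && mean(cur != snapshot) < tol) break
      snapshot <- cur
      if (sum(cur) > 0 && sum(cur) < n_px) phi <- signed_distance(cur)
    }
    inside <- phi < 0
    if (!any(inside) || all(inside)) break
    c_in <- mean(I[inside]); c_out <- mean(I[!inside])
    force_term <- (I - c_in)^2 - (I - c_out)^2
    # normalize the data force over the contour band so `dt` acts as a
    # boundary speed; far-field intensity extremes must not set the scale
    band <- abs(phi) < 2
    force_term <- force_term / max(abs(force_term[band]), .Machine$double.eps)
    curv <- pmin(pmax(curvature_field(phi), -1), 1)
    force_term <- force_term - mu * curv
    delta <- eps / (pi * (eps^2 + phi^2))
    phi <- pmin(pmax(phi + dt * delta * force_term, -5), 5)
    dim(phi) <- dim(I)
  }
  refined <- (phi < 0) * 1L
  dim(refined) <- dim(mask)
  if (sum(refined) == 0) {
    warning("level-set contour collapsed; returning the initial mask")
    return(list(mask = mask, phi = signed_distance(mask)))
  }
  lab <- EBImage::bwlabel(refined)
  sizes <- tabulate(as.vector(lab))
  refined <- (lab == which.max(sizes)) * 1L
  refined <- as.matrix(EBImage::fillHull(refined))
  storage.mode(refined) <- "integer"
  list(mask = refined, phi = phi)
}

#' Extract the lesion region of interest
#'
#' Tight bounding box of the mask foreground plus a margin, cropped from
#' the despeckled image (clipped at the image borders). Pixels outside
#' the mask are retained inside the crop so texture context survives;
#' the cropped mask is returned alongside.
#'
#' @param mask binary 0/1 matrix, non-empty.
#' @param image image to crop, same shape.
#' @param margin margin in pixels around the bounding box. Default 8.
#' @return list with `roi` (cropped image), `mask` (cropped mask) and
#'   `bbox` (`c(row_min, row_max, col_min, col_max)`).
#' @export
extract_roi <- function(mask, image, margin = 8L) {
  check_mask(mask)
  check_image(image)
  if (!all(dim(mask) == dim(image))) stop("mask/image shape mismatch", call. = FALSE)
  if (sum(mask) == 0) stop("`mask` is empty", call. = FALSE)
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  r1 <- max(1L, rows[1] - margin); r2 <- min(nrow(mask), rows[2] + margin)
  c1 <- max(1L, cols[1] - margin); c2 <- min(ncol(mask), cols[2] + margin)
  list(roi = image[r1:r2, c1:c2, drop = FALSE],
       mask = mask[r1:r2, c1:c2, drop = FALSE],
       bbox = c(row_min = r1, row_max = r2, col_min = c1, col_max = c2))
}

#' Segment a preprocessed image
#'
#' Convenience wrapper running [hybrid_cluster()], [binarize_lesion()]
#' and [level_set_refine()] in sequence.
#'
#' @param image despeckled numeric matrix.
#' @param M,fuzzifier clustering parameters, see [hybrid_cluster()].
#' @param levelset_iters level-set iteration budget. Default 200.
#' @param mu curvature weight. Default 0.2.
#' @return list with `mask` (refined), `initial_mask`, `clusters`,
#'   `phi`.
#' @export
segment_lesion <- function(image, M = 3L, fuzzifier = 2, levelset_iters = 200L,
                           mu = 0.2) {
  cl <- hybrid_cluster(image, M = M, fuzzifier = fuzzifier)
  mask0 <- binarize_lesion(cl, image)
  ref <- level_set_refine(mask0, image, max_iter = levelset_iters, mu = mu)
  list(mask = ref$mask, initial_mask = mask0, clusters = cl, phi = ref$phi)
}
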