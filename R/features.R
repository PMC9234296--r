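# Ordered boundary of a single-component mask, as an n x 2 matrix of
# (row, col) pixel coordinates (1-based). Uses EBImage contour tracing.
trace_boundary <- function(mask) {
  oc <- EBImage::ocontour(EBImage::bwlabel(mask))
  if (length(oc) == 0) stop("`mask` is empty", call. = FALSE)
  b <- oc[[1]] + 1L  # 0-based -> 1-based
  colnames(b) <- c("row", "col")
  b
}

# Chain-code perimeter with Vossepoel-Smeulders weights (0.980 axial,
# 1.406 diagonal), near-unbiased for smooth digital boundaries.
chain_perimeter <- function(boundary) {
  n <- nrow(boundary)
  if (n < 2) return(4)  # single pixel
  nxt <- rbind(boundary[-1, , drop = FALSE], boundary[1, , drop = FALSE])
  d <- abs(nxt - boundary)
  steps <- pmax(d[, 1], d[, 2])
  diag_step <- d[, 1] == 1 & d[, 2] == 1
  axial_step <- steps == 1 & !diag_step
  sum(axial_step) * 0.980 + sum(diag_step) * 1.406 +
    sum(steps[steps > 1])  # rare tracing jumps counted at unit weight
}

# Shoelace area of a closed polygon given as an n x 2 matrix.
polygon_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

#' Morphological (shape and border) features of a lesion mask
#'
#' Benign lesions tend to be smooth, round or oval; malignant lesions
#' irregular and spiculated. The nine descriptors quantify this:
#' area (px^2), perimeter (px, chain-code estimate), circularity
#' `4 pi A / P^2` (1 for a disk, lower for spiculated shapes), aspect
#' ratio and eccentricity from second-order moments, solidity (area /
#' convex-hull area), extent (area / bounding-box area), convexity
#' (convex perimeter / perimeter) and boundary roughness (coefficient of
#' variation of the centroid-to-boundary radial distance).
#'
#' @param mask binary 0/1 matrix containing a single connected
#'   component.
#' @return named numeric vector of length 9.
#' @export
morphological_features <- function(mask) {
  check_mask(mask)
  area <- sum(mask)
  if (area == 0) stop("`mask` is empty", call. = FALSE)
  boundary <- trace_boundary(mask)
  perim <- chain_perimeter(boundary)
  idx <- which(mask == 1, arr.ind = TRUE)
  centroid <- colMeans(idx)
  # second-order central moments -> principal axes
  if (nrow(idx) > 1) {
    cv <- stats::cov(idx) * (nrow(idx) - 1) / nrow(idx)
    ev <- sort(eigen(cv, symmetric = TRUE, only.values = TRUE)$values,
               decreasing = TRUE)
    ev <- pmax(ev, 1 / 12)  # single-pixel row/col: variance of a unit pixel
  } else {
    ev <- c(1 / 12, 1 / 12)
  }
  aspect <- sqrt(ev[1] / ev[2])
  ecc <- sqrt(1 - ev[2] / ev[1])
  # convex hull over pixel corners so a filled rectangle has solidity 1
  corners <- rbind(boundary + cbind(rep(-0.5, nrow(boundary)), -0.5),
                   boundary + cbind(rep(-0.5, nrow(boundary)), 0.5),
                   boundary + cbind(rep(0.5, nrow(boundary)), -0.5),
                   boundary + cbind(rep(0.5, nrow(boundary)), 0.5))
  hull <- corners[chull(corners), , drop = FALSE]
  hull_area <- polygon_area(hull)
  hull_perim <- {
    nxt <- rbind(hull[-1, , drop = FALSE], hull[1, , drop = FALSE])
    sum(sqrt(rowSums((nxt - hull)^2)))
  }
  bbox_area <- prod(apply(idx, 2, function(v) diff(range(v)) + 1))
  rd <- sqrt(rowSums((boundary - matrix(centroid, nrow(boundary), 2,
                                        byrow = TRUE))^2))
  roughness <- if (mean(rd) > 0) stats::sd(rd) / mean(rd) else 0
  c(area = area,
    perimeter = perim,
    circularity = 4 * pi * area / perim^2,
    aspect_ratio = aspect,
    eccentricity = ecc,
    solidity = min(area / hull_area, 1),
    extent = area / bbox_area,
    convexity = min(hull_perim / perim, 1),
    roughness = roughness)
}

glcm_offsets <- function() {
  # unit-distance offsets at 0, 45, 90, 135 degrees in (drow, dcol)
  list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
       `135` = c(-1L, -1L))
}

glcm_stats <- function(P, levels) {
  i <- matrix(0:(levels - 1), levels, levels)
  j <- t(i)
  contrast <- sum((i - j)^2 * P)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  s_i <- sqrt(sum((i - mu_i)^2 * P)); s_j <- sqrt(sum((j - mu_j)^2 * P))
  correlation <- if (s_i > 1e-12 && s_j > 1e-12) {
    sum((i - mu_i) * (j - mu_j) * P) / (s_i * s_j)
  } else 0  # degenerate (constant) region: no linear structure to report
  energy <- sum(P^2)
  homogeneity <- sum(P / (1 + (i - j)^2))
  pz <- P[P > 0]
  entropy <- -sum(pz * log2(pz))
  c(contrast = contrast, correlation = correlation, energy = energy,
    homogeneity = homogeneity, entropy = entropy)
}

#' Grey-level co-occurrence (Haralick) texture features
#'
#' Quantizes the masked region of interest to `levels` grey levels by
#' min-max scaling, accumulates a symmetric normalized co-occurrence
#' matrix for each unit-distance offset (0, 45, 90, 135 degrees; both
#' pixels of a pair must lie inside the mask), and computes contrast,
#' correlation, energy (angular second moment), homogeneity and entropy
#' (bits) per offset. A constant region follows the degenerate path:
#' one co-occurrence cell, so energy 1, contrast 0, entropy 0.
#'
#' @param roi numeric matrix (region-of-interest crop).
#' @param mask binary 0/1 matrix of the same shape.
#' @param levels number of grey levels. Default 32.
#' @param average if `TRUE`, return the 5 statistics averaged over
#'   offsets; otherwise (default) the 20 per-offset values.
#' @return named numeric vector (`<stat>_<angle>` or `<stat>`).
#' @export
glcm_features <- function(roi, mask, levels = 32L, average = FALSE) {
  check_image(roi, arg = "roi")
  check_mask(mask)
  if (!all(dim(roi) == dim(mask))) stop("roi/mask shape mismatch", call. = FALSE)
  inside <- mask == 1
  if (sum(inside) < 2) stop("mask must cover at least 2 pixels", call. = FALSE)
  vals <- roi[inside]
  rng <- range(vals)
  q <- matrix(0L, nrow(roi), ncol(roi))
  if (diff(rng) > 0) {
    q[inside] <- pmin(as.integer(floor((roi[inside] - rng[1]) / diff(rng) * levels)),
                      levels - 1L)
  }
  h <- nrow(roi); w <- ncol(roi)
  per_offset <- lapply(glcm_offsets(), function(off) {
    dr <- off[1]; dc <- off[2]
    r_src <- seq_len(h); c_src <- seq_len(w)
    r_ok <- r_src + dr >= 1 & r_src + dr <= h
    c_ok <- c_src + dc >= 1 & c_src + dc <= w
    src <- as.matrix(expand.grid(r = r_src[r_ok], c = c_src[c_ok]))
    dst <- cbind(src[, 1] + dr, src[, 2] + dc)
    ok <- inside[src] & inside[dst]
    if (!any(ok)) return(glcm_stats(matrix(1, 1, 1), 1L))
    a <- q[src][ok]; b <- q[dst][ok]
    counts <- tabulate(a * levels + b + 1L, nbins = levels^2) +
              tabulate(b * levels + a + 1L, nbins = levels^2)  # symmetric
    P <- matrix(counts / sum(counts), levels, levels)
    glcm_stats(P, levels)
  })
  if (average) {
    return(Reduce(`+`, per_offset) / length(per_offset))
  }
  stats_names <- names(per_offset[[1]])
  out <- unlist(lapply(stats_names, function(s) {
    v <- vapply(per_offset, `[[`, numeric(1), s)
    setNames(v, paste0(s, "_", names(per_offset)))
  }))
  out
}

#' First-order intensity statistics of the masked region
#'
#' Mean, population variance, skewness and excess kurtosis over the
#' masked pixels. On a zero-variance region skewness and kurtosis are
#' reported as 0 by convention.
#'
#' @param roi numeric matrix.
#' @param mask binary 0/1 matrix of the same shape with >= 2 foreground
#'   pixels.
#' @return named numeric vector `fo_mean`, `fo_variance`, `fo_skewness`,
#'   `fo_kurtosis`.
#' @export
first_order_features <- function(roi, mask) {
  check_image(roi, arg = "roi")
  check_mask(mask)
  if (!all(dim(roi) == dim(mask))) stop("roi/mask shape mismatch", call. = FALSE)
  v <- roi[mask == 1]
  if (length(v) < 2) stop("mask must cover at least 2 pixels", call. = FALSE)
  m <- mean(v)
  m2 <- mean((v - m)^2)
  if (m2 < 1e-24) {
    return(c(fo_mean = m, fo_variance = 0, fo_skewness = 0, fo_kurtosis = 0))
  }
  m3 <- mean((v - m)^3)
  m4 <- mean((v - m)^4)
  c(fo_mean = m, fo_variance = m2, fo_skewness = m3 / m2^1.5,
    fo_kurtosis = m4 / m2^2 - 3)
}

#' Feature schema: fixed column order of the fused feature vector
#'
#' Nine morphology descriptors, then the grey-level co-occurrence
#' statistics per offset (feature-major: all contrasts, then all
#' correlations, ...), then the four first-order moments.
#'
#' @return character vector of 33 feature names (with the defaults).
#' @export
feature_schema <- function() {
  morph <- c("area", "perimeter", "circularity", "aspect_ratio",
             "eccentricity", "solidity", "extent", "convexity", "roughness")
  glcm <- unlist(lapply(c("contrast", "correlation", "energy",
                          "homogeneity", "entropy"),
                        function(s) paste(s, c("0", "45", "90", "135"),
                                          sep = "_")))
  fo <- c("fo_mean", "fo_variance", "fo_skewness", "fo_kurtosis")
  c(morph, glcm, fo)
}

#' Fuse morphology, texture and first-order features
#'
#' Concatenates the three partial vectors in the documented
#' [feature_schema()] order and validates names and lengths.
#'
#' @param morph result of [morphological_features()].
#' @param texture result of [glcm_features()] (per-offset form).
#' @param first_order result of [first_order_features()].
#' @return named numeric vector following [feature_schema()].
#' @export
fuse_features <- function(morph, texture, first_order) {
  v <- c(morph, texture, first_order)
  schema <- feature_schema()
  if (length(v) != length(schema) || !all(names(v) == schema)) {
    stop("fused feature vector does not match the schema", call. = FALSE)
  }
  if (!all(is.finite(v))) stop("non-finite feature value", call. = FALSE)
  v
}

#' Extract the full fused feature vector of one segmented lesion
#'
#' @param roi region-of-interest crop of the despeckled image.
#' @param mask cropped lesion mask.
#' @param levels grey levels for the co-occurrence features.
#' @return named numeric vector following [feature_schema()].
#' @export
extract_features <- function(roi, mask, levels = 32L) {
  fuse_features(morphological_features(mask),
                glcm_features(roi, mask, levels = levels),
                first_order_features(roi, mask))
}

#' Fit per-column z-score standardization on training rows
#'
#' @param table data.frame or matrix of numeric feature columns
#'   (training rows only).
#' @return list with `mean` and `sd` per column (zero-variance columns
#'   get sd 1 so they standardize to 0).
#' @export
standardize_fit <- function(table) {
  x <- as.matrix(table)
  mu <- colMeans(x)
  s <- apply(x, 2, stats::sd)
  s[!is.finite(s) | s < 1e-12] <- 1
  list(mean = mu, sd = s)
}

#' Apply fitted standardization statistics
#'
#' @param table data.frame or matrix with the same columns the
#'   statistics were fitted on.
#' @param stats result of [standardize_fit()].
#' @return standardized numeric matrix.
#' @export
standardize_apply <- function(table, stats) {
  x <- as.matrix(table)
  sweep(sweep(x, 2, stats$mean, `-`), 2, stats$sd, `/`)
}

#' Fit PCA and project the feature table
#'
#' Principal component analysis on standardized features, keeping the
#' smallest number of components whose cumulative explained variance
#' reaches `retained_variance`. The transform is mean-centering followed
#' by projection on the retained directions; it must be fitted on
#' training rows only.
#'
#' @param table standardized numeric matrix (rows = samples).
#' @param retained_variance target cumulative explained-variance ratio
#'   in `(0, 1]`. Default 0.95.
#' @return list with `model` (class `uscad_pca`: `means`, `rotation`,
#'   `ratios`, `k`) and `scores` (projected table, `k` columns).
#' @export
pca_fit_transform <- function(table, retained_variance = 0.95) {
  x <- as.matrix(table)
  if (nrow(x) < 2) stop("need at least 2 samples", call. = FALSE)
  if (retained_variance <= 0 || retained_variance > 1) {
    stop("`retained_variance` must lie in (0, 1]", call. = FALSE)
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  ratios <- pc$sdev^2 / sum(pc$sdev^2)
  k <- which(cumsum(ratios) >= retained_variance - 1e-12)[1]
  model <- structure(list(means = pc$center, rotation = pc$rotation,
                          ratios = ratios, k = k),
                     class = "uscad_pca")
  list(model = model, scores = pc$x[, seq_len(k), drop = FALSE])
}

#' Project new rows with a fitted PCA model
#'
#' @param model object of class `uscad_pca`.
#' @param table numeric matrix with the columns the model was fitted on.
#' @return projected matrix with `model$k` columns.
#' @export
pca_transform <- function(model, table) {
  stopifnot(inherits(model, "uscad_pca"))
  x <- sweep(as.matrix(table), 2, model$means, `-`)
  x %*% model$rotation[, seq_len(model$k), drop = FALSE]
}

#' @export
print.uscad_pca <- function(x, ...) {
  cat(sprintf("uscad_pca: %d/%d components, %.1f%% variance retained\n",
              x$k, length(x$ratios), 100 * sum(x$ratios[seq_len(x$k)])))
  invisible(x)
}
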