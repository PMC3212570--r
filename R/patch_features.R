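#' Partition an image into a patch grid
#'
#' Tiles the image with non-overlapping square patches (default 20 x 20 px,
#' the classification unit of the pipeline). If a dimension is not a
#' multiple of `patch_size` the image is reflect-padded on the bottom/right
#' to the next multiple, so narrow marginal regions are never truncated.
#' Windows are half-open in 0-based pixel coordinates:
#' patch (r, c) covers rows `[r*s, (r+1)*s)` and columns `[c*s, (c+1)*s)`.
#'
#' @param image a [calibrated_image].
#' @param patch_size side length in pixels (>= 4).
#' @return a `patch_grid`: `n_rows`, `n_cols`, `patch_size`, the padded
#'   intensity matrix `padded`, and the original image size `image_size`.
#' @examples
#' img <- calibrated_image(matrix(runif(100 * 100), 100), 1)
#' g <- build_patch_grid(img, 20)   # 5 x 5 = 25 patches
#' c(g$n_rows, g$n_cols)
#' @export
build_patch_grid <- function(image, patch_size = 20L) {
  stopifnot(inherits(image, "calibrated_image"))
  patch_size <- as.integer(patch_size)
  if (patch_size < 4) stopf("`patch_size` must be >= 4")
  m <- image$intensities
  if (nrow(m) < 4 || ncol(m) < 4) stopf("image smaller than 4 x 4")
  pad_to <- function(n) as.integer(ceiling(n / patch_size) * patch_size)
  ph <- pad_to(nrow(m)); pw <- pad_to(ncol(m))
  reflect_idx <- function(n, target) {
    if (target == n) return(seq_len(n))
    extra <- target - n
    if (extra > n - 1) stopf("image too small to reflect-pad to a full patch")
    c(seq_len(n), seq(n - 1, by = -1, length.out = extra))
  }
  padded <- m[reflect_idx(nrow(m), ph), reflect_idx(ncol(m), pw), drop = FALSE]
  structure(list(patch_size = patch_size,
                 n_rows = ph %/% patch_size, n_cols = pw %/% patch_size,
                 padded = padded, image_size = dim(m)),
            class = "patch_grid")
}

# 0-based (r, c) patch -> 1-based pixel index ranges on the padded image.
patch_window <- function(grid, r, c) {
  s <- grid$patch_size
  list(rows = (r * s + 1L):((r + 1L) * s), cols = (c * s + 1L):((c + 1L) * s))
}

#' Configuration of the per-patch feature sets
#'
#' Five texture feature families are extracted per patch; any can be
#' re-parameterized here (bin counts, smoothing scales) so that alternative
#' definitions can be swapped in without touching the classifiers.
#'
#' @param intensity_bins bins of F1, the intensity histogram on \[0, 1\].
#' @param gradient_bins bins of F2, the gradient-magnitude histogram on
#'   \[0, max theoretical central-difference magnitude\].
#' @param orientation_bins bins of F3, the magnitude-weighted gradient
#'   orientation histogram on \[-pi, pi).
#' @param variance_sigmas Gaussian smoothing scales (px) of F4, the
#'   multi-scale standard-deviation vector.
#' @return a list of class `patch_feature_config`.
#' @export
patch_feature_config <- function(intensity_bins = 16L, gradient_bins = 16L,
                                 orientation_bins = 8L,
                                 variance_sigmas = c(0, 1, 2, 4)) {
  structure(list(intensity_bins = as.integer(intensity_bins),
                 gradient_bins = as.integer(gradient_bins),
                 orientation_bins = as.integer(orientation_bins),
                 variance_sigmas = as.numeric(variance_sigmas)),
            class = "patch_feature_config")
}

feature_set_lengths <- function(config) {
  c(F1 = config$intensity_bins, F2 = config$gradient_bins,
    F3 = config$orientation_bins, F4 = length(config$variance_sigmas), F5 = 2L)
}

# L1-normalized histogram with fixed edges; counts below/above range clamp
# into the first/last bin so mass is never dropped.
fixed_histogram <- function(x, lo, hi, nbins, weights = NULL) {
  idx <- 1L + floor((x - lo) / (hi - lo) * nbins)
  idx <- clamp(idx, 1L, nbins)
  if (is.null(weights)) weights <- rep(1, length(x))
  h <- as.vector(tapply(weights, factor(idx, levels = seq_len(nbins)), sum))
  h[is.na(h)] <- 0
  tot <- sum(h)
  if (tot > 0) h / tot else rep(1 / nbins, nbins)
}

#' Extract the five per-patch feature sets
#'
#' Per patch: F1 = intensity histogram; F2 = central-difference
#' gradient-magnitude histogram; F3 = gradient-orientation histogram
#' weighted by magnitude; F4 = sample standard deviation of patch
#' intensities after Gaussian smoothing at each configured scale; F5 =
#' edge-pixel fraction (gradient magnitude above the image-global Otsu
#' level of gradient magnitudes) and mean absolute Laplacian. Histogram
#' edges are fixed (\[0, 1\] for intensity; \[0, sqrt(2)/2\] for
#' central-difference magnitudes) so features are comparable across images;
#' F1-F3 each sum to 1.
#'
#' @param image a [calibrated_image] (the one the grid was built from).
#' @param grid a [build_patch_grid] result.
#' @param config a [patch_feature_config].
#' @return a `patch_feature_sets` object: list of matrices `F1`..`F5`, one
#'   row per patch in row-major (r, c) order, plus the grid and config.
#' @export
extract_feature_sets <- function(image, grid, config = patch_feature_config()) {
  stopifnot(inherits(image, "calibrated_image"), inherits(grid, "patch_grid"))
  if (!identical(dim(image$intensities), grid$image_size))
    stopf("grid was not built from this image")
  m <- grid$padded
  s <- grid$patch_size
  g <- image_gradient(m)
  ori <- atan2(g$gy, g$gx)
  lap <- abs(image_laplacian(m))
  grad_hi <- sqrt(2) / 2  # max central-difference magnitude for [0,1] data
  mag_vec <- as.vector(g$mag)
  edge_level <- if (max(mag_vec) > min(mag_vec)) otsu_threshold(mag_vec) else Inf
  smoothed <- lapply(config$variance_sigmas, function(sg) gaussian_smooth(m, sg))

  n_patches <- grid$n_rows * grid$n_cols
  F1 <- matrix(0, n_patches, config$intensity_bins)
  F2 <- matrix(0, n_patches, config$gradient_bins)
  F3 <- matrix(0, n_patches, config$orientation_bins)
  F4 <- matrix(0, n_patches, length(config$variance_sigmas))
  F5 <- matrix(0, n_patches, 2L)
  i <- 0L
  for (r in 0:(grid$n_rows - 1L)) {
    for (c in 0:(grid$n_cols - 1L)) {
      i <- i + 1L
      w <- patch_window(grid, r, c)
      px <- m[w$rows, w$cols]
      pmag <- g$mag[w$rows, w$cols]
      pori <- ori[w$rows, w$cols]
      F1[i, ] <- fixed_histogram(as.vector(px), 0, 1, config$intensity_bins)
      F2[i, ] <- fixed_histogram(as.vector(pmag), 0, grad_hi, config$gradient_bins)
      wsum <- sum(pmag)
      F3[i, ] <- if (wsum > 0)
        fixed_histogram(as.vector(pori), -pi, pi, config$orientation_bins,
                        weights = as.vector(pmag))
      else rep(1 / config$orientation_bins, config$orientation_bins)
      F4[i, ] <- vapply(smoothed, function(sm) sd(as.vector(sm[w$rows, w$cols])),
                        numeric(1))
      F5[i, 1] <- mean(pmag > edge_level)
      F5[i, 2] <- mean(lap[w$rows, w$cols])
    }
  }
  structure(list(F1 = F1, F2 = F2, F3 = F3, F4 = F4, F5 = F5,
                 grid = grid, config = config),
            class = "patch_feature_sets")
}

# Row-major (r, c) -> feature-matrix row index (0-based r, c).
patch_index <- function(grid, r, c) r * grid$n_cols + c + 1L

#' Export per-patch features as a flat data.frame
#'
#' One row per patch: image id, 0-based grid coordinates, and the
#' concatenated F1..F5 entries — convenient for CSV export and offline
#' inspection.
#'
#' @param features a [extract_feature_sets] result.
#' @param image_id identifier recorded in the first column.
#' @return a data.frame.
#' @export
features_as_data_frame <- function(features, image_id = "image") {
  grid <- features$grid
  coords <- expand.grid(c = 0:(grid$n_cols - 1L), r = 0:(grid$n_rows - 1L))
  mats <- lapply(c("F1", "F2", "F3", "F4", "F5"), function(nm) {
    mat <- features[[nm]]
    colnames(mat) <- paste0(nm, "_", seq_len(ncol(mat)))
    mat
  })
  cbind(data.frame(image_id = image_id, r = coords$r, c = coords$c),
        as.data.frame(do.call(cbind, mats)))
}
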