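# Scatter-assay scoring: resolution normalization to 5 um/px, a 10-bin
# rotation-invariant uniform local binary pattern (LBP, P = 8, R = 1)
# histogram over cellular pixels, and SVM classification under
# leave-one-out and constrained split-resampling validation.

#' Downsample an image to a target physical resolution
#'
#' Local-mean block reduction by the integer factor nearest to
#' `target / pixel_size`, followed by a bilinear resize to hit the exact
#' target. Upsampling is refused: texture statistics are only comparable
#' when every image is reduced to the common scale.
#'
#' @param image a [calibrated_image].
#' @param target_um_per_px target pixel size (default 5 um, the common
#'   scale of the scatter descriptor).
#' @return a [calibrated_image] at the target resolution.
#' @export
resample_to_target <- function(image, target_um_per_px = 5) {
  ps <- image$pixel_size_um
  if (ps > target_um_per_px * (1 + 1e-9))
    stopf("input resolution (%g um/px) is coarser than the target (%g um/px); upsampling is not supported",
          ps, target_um_per_px)
  if (abs(ps - target_um_per_px) < 1e-9 * target_um_per_px) return(image)
  k <- max(1L, as.integer(round(target_um_per_px / ps)))
  m <- image$intensities
  h <- (nrow(m) %/% k) * k; w <- (ncol(m) %/% k) * k
  m <- m[seq_len(h), seq_len(w), drop = FALSE]
  # block mean via row/col group sums
  rm <- rowsum(m, rep(seq_len(h %/% k), each = k)) / k
  bm <- t(rowsum(t(rm), rep(seq_len(w %/% k), each = k))) / k
  ps_block <- ps * k
  if (abs(ps_block - target_um_per_px) > 1e-9 * target_um_per_px) {
    scale <- ps_block / target_um_per_px
    out_h <- max(1L, as.integer(round(nrow(bm) * scale)))
    out_w <- max(1L, as.integer(round(ncol(bm) * scale)))
    bm <- as.matrix(EBImage::resize(bm, w = out_h, h = out_w,
                                    filter = "bilinear"))
  }
  calibrated_image(clamp(bm, 0, 1), pixel_size_um = target_um_per_px,
                   normalize = FALSE)
}

# riu2 mapping table for 8-bit patterns: code = popcount if the circular
# pattern has <= 2 transitions, else 9.
lbp_riu2_table <- function() {
  codes <- integer(256)
  for (pat in 0:255) {
    bits <- as.integer(intToBits(pat)[1:8])
    trans <- sum(bits != c(bits[-1], bits[1]))
    codes[pat + 1] <- if (trans <= 2) sum(bits) else 9L
  }
  codes
}

#' Per-pixel rotation-invariant uniform LBP codes
#'
#' Compares each interior pixel to its 8 neighbors on the radius-1 circle
#' (diagonal sample points bilinearly interpolated); neighbor >= center
#' maps to 1. The 8-bit pattern is reduced to the rotation-invariant
#' uniform code: the number of 1 bits when the circular pattern has at most
#' 2 transitions, otherwise 9. Border pixels lacking a full neighborhood
#' are `NA`.
#'
#' @param intensities numeric image matrix.
#' @return integer matrix of codes 0..9 (`NA` on the 1-px border).
#' @export
lbp_codes <- function(intensities) {
  m <- intensities
  h <- nrow(m); w <- ncol(m)
  if (h < 3 || w < 3) stopf("image too small for a 3 x 3 neighborhood")
  ri <- 2:(h - 1); ci <- 2:(w - 1)
  ctr <- m[ri, ci, drop = FALSE]
  d <- sqrt(2) / 2  # radius-1 diagonal offset
  bil <- function(dr, dc) {
    r0 <- floor(dr); c0 <- floor(dc)
    fr <- dr - r0; fc <- dc - c0
    (1 - fr) * (1 - fc) * m[ri + r0, ci + c0, drop = FALSE] +
      fr * (1 - fc) * m[ri + r0 + 1, ci + c0, drop = FALSE] +
      (1 - fr) * fc * m[ri + r0, ci + c0 + 1, drop = FALSE] +
      fr * fc * m[ri + r0 + 1, ci + c0 + 1, drop = FALSE]
  }
  # circular order: E, NE, N, NW, W, SW, S, SE
  offs <- list(c(0, 1), c(-d, d), c(-1, 0), c(-d, -d),
               c(0, -1), c(d, -d), c(1, 0), c(d, d))
  pattern <- matrix(0L, length(ri), length(ci))
  for (k in seq_along(offs)) {
    o <- offs[[k]]
    nb <- if (all(o == round(o))) m[ri + o[1], ci + o[2], drop = FALSE]
          else bil(o[1], o[2])
    pattern <- pattern + bitwShiftL(as.integer(nb >= ctr), k - 1L)
  }
  table <- lbp_riu2_table()
  out <- matrix(NA_integer_, h, w)
  out[ri, ci] <- table[pattern + 1L]
  out
}

#' LBP texture descriptor of the cellular regions
#'
#' The L1-normalized 10-bin histogram of rotation-invariant uniform LBP
#' codes over all cellular pixels — a gray-scale invariant, zero-parameter
#' texture summary of the multi-cellular regions. Bins 0..8 are the
#' uniform patterns with that many 1 bits; bin 9 collects non-uniform
#' patterns.
#'
#' @param image a [calibrated_image].
#' @param cell_mask a [segmentation_mask] of the image (`TRUE` =
#'   background); cellular pixels are its complement.
#' @return a `scatter_descriptor`: numeric vector of length 10 summing
#'   to 1.
#' @export
scatter_descriptor <- function(image, cell_mask) {
  if (!identical(dim(image$intensities), dim(cell_mask)))
    stopf("image and mask shapes differ")
  codes <- lbp_codes(image$intensities)
  sel <- !unclass(cell_mask) & !is.na(codes)
  if (!any(sel)) stopf("no cellular pixels with a full LBP neighborhood")
  counts <- tabulate(codes[sel] + 1L, nbins = 10L)
  structure(counts / sum(counts), names = paste0("lbp", 0:9),
            class = "scatter_descriptor")
}

#' Reduce a descriptor to selected bins
#'
#' @param d a [scatter_descriptor] (or length-10 vector).
#' @param bins 0-based bin indices (default the most discriminative subset
#'   `{6, 7, 9}`).
#' @return the selected entries in the order given.
#' @export
reduced_descriptor <- function(d, bins = c(6L, 7L, 9L)) {
  if (any(bins < 0 | bins > 9)) stopf("bins must lie in 0..9")
  unclass(d)[bins + 1L]
}

#' Compute a scatter descriptor from a raw image
#'
#' The full scoring front-end: downsample to the common 5 um/px scale,
#' segment cellular regions with a trained model, then extract the LBP
#' histogram over the cellular pixels of the final mask.
#'
#' @param image a [calibrated_image] (native resolution).
#' @param seg_model a `multicellseg_model` (typically trained on scatter
#'   images).
#' @param target_um_per_px descriptor scale.
#' @param ... passed to [segment_image].
#' @return a `scatter_descriptor`.
#' @export
scatter_descriptor_from_image <- function(image, seg_model,
                                          target_um_per_px = 5, ...) {
  small <- resample_to_target(image, target_um_per_px)
  res <- segment_image(seg_model, small, ...)
  scatter_descriptor(small, res$mask_final)
}

fit_scatter_svm <- function(X, scattered, C = 1, standardize = TRUE) {
  std <- if (standardize) standardizer(X)
         else list(center = rep(0, ncol(X)), scale = rep(1, ncol(X)))
  hp <- fit_linear_hyperplane(apply_standardizer(X, std), scattered, C = C)
  list(hp = hp, std = std)
}

#' Leave-one-out scatter classification
#'
#' For each image an SVM is trained on all other images and the left-out
#' image's signed confidence is recorded; the default decision threshold
#' is confidence zero.
#'
#' @param descriptors matrix, one row per image (full or reduced
#'   descriptor).
#' @param labels logical vector (`TRUE` = scattered).
#' @param seed integer seed (kept for interface symmetry; the procedure is
#'   deterministic).
#' @param C linear SVM cost.
#' @param standardize standardize descriptors before fitting?
#' @return data.frame: `confidence`, `predicted`, `label`; attribute
#'   `accuracy`.
#' @export
loo_classify <- function(descriptors, labels, seed = 1L, C = 1,
                         standardize = TRUE) {
  X <- as.matrix(descriptors)
  n <- nrow(X)
  if (sum(labels) < 2 || sum(!labels) < 2)
    stopf("need at least 2 images per class")
  conf <- numeric(n)
  for (i in seq_len(n)) {
    m <- fit_scatter_svm(X[-i, , drop = FALSE], labels[-i], C, standardize)
    conf[i] <- hyperplane_distance(
      apply_standardizer(X[i, , drop = FALSE], m$std), m$hp)
  }
  out <- data.frame(confidence = conf, predicted = conf > 0, label = labels)
  attr(out, "accuracy") <- mean(out$predicted == labels)
  out
}

#' Repeated constrained equal-split validation
#'
#' Randomly partitions the images into equal-size train and test halves,
#' requiring strictly more than `min_minority_train` minority-class images
#' in the training half; trains an SVM on the training half and records
#' test accuracy. Repeated `n_repeats` times with independent splits.
#'
#' @param descriptors matrix, one row per image.
#' @param labels logical vector (`TRUE` = scattered).
#' @param n_repeats number of random splits (default 100).
#' @param min_minority_train the training half must contain more than this
#'   many minority-class images (default 3).
#' @param seed integer seed.
#' @param C,standardize SVM settings as in [loo_classify].
#' @return numeric vector of per-split test accuracies.
#' @export
split_validate <- function(descriptors, labels, n_repeats = 100L,
                           min_minority_train = 3L, seed = 1L, C = 1,
                           standardize = TRUE) {
  X <- as.matrix(descriptors)
  n <- nrow(X)
  n_train <- n %/% 2L
  minority <- if (sum(labels) <= sum(!labels)) labels else !labels
  if (sum(minority) < min_minority_train + 2L)
    stopf("class constraint unsatisfiable: too few minority images for train and test")
  with_seed(seed, vapply(seq_len(n_repeats), function(rep) {
    repeat {
      tr <- sample.int(n, n_train)
      if (sum(minority[tr]) > min_minority_train &&
          sum(minority[-tr]) >= 1L &&
          length(unique(labels[tr])) == 2L) break
    }
    m <- fit_scatter_svm(X[tr, , drop = FALSE], labels[tr], C, standardize)
    conf <- hyperplane_distance(
      apply_standardizer(X[-tr, , drop = FALSE], m$std), m$hp)
    mean((conf > 0) == labels[-tr])
  }, numeric(1)))
}
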