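#' Parameters for the synthetic image generator
#'
#' The generator emulates the appearance that drives the segmentation
#' problem: cellular regions carry band-limited texture (smoothed Gaussian
#' noise at a 2-4 px correlation length modulated by a coarser bright/dark
#' blob field, standing in for cell-scale granularity), while background
#' ("non-occupied") regions are smooth except for sensor noise and a slow
#' illumination gradient. The wound/background boundary is displaced by a
#' sinusoid plus low-frequency noise so it is never a trivially learnable
#' straight line.
#'
#' @param image_size integer (H, W) in pixels; at least 64 x 64.
#' @param pixel_size_um physical pixel size, micrometres per pixel.
#' @param cell_texture_strength standard deviation of the fine cellular
#'   texture, in intensity units of the \[0, 1\] range (>= 0).
#' @param background_noise_sd standard deviation of the additive Gaussian
#'   sensor noise applied to every pixel.
#' @param illumination_gradient total intensity drop of a linear shading
#'   ramp across the image, as a fraction of the dynamic range.
#' @param wound_shape `"vertical-band"` (a scratch), `"blob"` (a closed
#'   cell-free region), or `"none"`.
#' @param wound_area_fraction target fraction of background pixels, in
#'   \[0, 1).
#' @param rng_seed integer seed; identical seeds give bit-identical output.
#' @return a list of class `synth_params`.
#' @export
synth_params <- function(image_size = c(200L, 200L),
                         pixel_size_um = 1.24,
                         cell_texture_strength = 0.12,
                         background_noise_sd = 0.02,
                         illumination_gradient = 0.1,
                         wound_shape = c("vertical-band", "blob", "none"),
                         wound_area_fraction = 0.3,
                         rng_seed = 1L) {
  wound_shape <- match.arg(wound_shape)
  if (length(image_size) != 2 || any(image_size < 64))
    stopf("`image_size` must be (H, W) with both >= 64")
  if (wound_area_fraction < 0 || wound_area_fraction >= 1)
    stopf("`wound_area_fraction` must lie in [0, 1)")
  if (cell_texture_strength < 0 || background_noise_sd < 0)
    stopf("texture strength and noise sd must be >= 0")
  if (pixel_size_um <= 0) stopf("`pixel_size_um` must be > 0")
  structure(list(image_size = as.integer(image_size),
                 pixel_size_um = pixel_size_um,
                 cell_texture_strength = cell_texture_strength,
                 background_noise_sd = background_noise_sd,
                 illumination_gradient = illumination_gradient,
                 wound_shape = wound_shape,
                 wound_area_fraction = wound_area_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "synth_params")
}

ground_truth_pair <- function(image, mask) {
  stopifnot(identical(dim(image$intensities), dim(mask)))
  structure(list(image = image, mask = mask), class = "ground_truth_pair")
}

# Smooth zero-mean unit-sd random field (correlation set by sigma).
smooth_field <- function(h, w, sigma) {
  f <- gaussian_smooth(matrix(rnorm(h * w), h, w), sigma)
  s <- sd(as.vector(f))
  if (s < 1e-12) return(matrix(0, h, w))
  (f - mean(f)) / s
}

# Irregular displacement profile along an edge of length n (pixels).
edge_displacement <- function(n, amplitude) {
  if (amplitude <= 0) return(rep(0, n))
  phase <- runif(1, 0, 2 * pi)
  k <- runif(1, 1.5, 3.5)
  sine <- sin(2 * pi * k * seq_len(n) / n + phase)
  noise <- gaussian_smooth_1d(rnorm(n), n / 20)
  noise <- if (sd(noise) < 1e-12) rep(0, n) else (noise - mean(noise)) / sd(noise)
  amplitude * (0.6 * sine + 0.4 * noise)
}

# Background mask (TRUE = background) for the requested wound geometry.
wound_mask <- function(h, w, shape, fraction) {
  if (shape == "none" || fraction <= 0) return(matrix(FALSE, h, w))
  if (shape == "vertical-band") {
    hw <- fraction * w / 2
    amp <- min(0.05 * w, 0.8 * hw)
    left <- w / 2 - hw + edge_displacement(h, amp)
    right <- w / 2 + hw + edge_displacement(h, amp)
    cols <- matrix(seq_len(w), h, w, byrow = TRUE)
    cols > matrix(left, h, w) & cols <= matrix(right, h, w)
  } else { # blob
    r0 <- sqrt(fraction * h * w / pi)
    cy <- h / 2; cx <- w / 2
    yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    theta <- atan2(yy - cy, xx - cx)
    nseg <- 64L
    prof <- edge_displacement(nseg, 0.12 * r0)
    idx <- pmin(nseg, 1L + floor((theta + pi) / (2 * pi) * nseg))
    rad <- r0 + matrix(prof[idx], h, w)
    sqrt((yy - cy)^2 + (xx - cx)^2) <= rad
  }
}

# Paint an image given a cellular-pixel indicator. Class-specific texture
# parameters let the scatter generator use distinct texture statistics.
paint_image <- function(cellular, params, fine_sigma = 1.5, blob_sigma = 5,
                        strength = NULL) {
  h <- nrow(cellular); w <- ncol(cellular)
  strength <- strength %||% params$cell_texture_strength
  base <- matrix(0.55, h, w)
  base[cellular] <- 0.45
  fine <- smooth_field(h, w, fine_sigma) * strength
  blobs <- smooth_field(h, w, blob_sigma) * 0.6 * strength
  tex <- fine + blobs
  tex[!cellular] <- 0
  ramp <- matrix(seq(0, params$illumination_gradient, length.out = w),
                 h, w, byrow = TRUE)
  noise <- matrix(rnorm(h * w, sd = params$background_noise_sd), h, w)
  clamp(base + tex + ramp + noise, 0, 1)
}

#' Generate a synthetic wound image with exact ground truth
#'
#' @param params a [synth_params] object.
#' @return a `ground_truth_pair`: `$image` a [calibrated_image], `$mask` a
#'   truth [segmentation_mask] (`TRUE` = background).
#' @examples
#' pair <- generate_wound_image(synth_params(rng_seed = 3))
#' mean(pair$mask)   # ~ wound_area_fraction
#' @export
generate_wound_image <- function(params) {
  stopifnot(inherits(params, "synth_params"))
  h <- params$image_size[1]; w <- params$image_size[2]
  with_seed(params$rng_seed, {
    bg <- wound_mask(h, w, params$wound_shape, params$wound_area_fraction)
    img <- paint_image(!bg, params)
    ground_truth_pair(
      calibrated_image(img, params$pixel_size_um, normalize = FALSE),
      segmentation_mask(bg, stage = "truth"))
  })
}

#' Generate a time-lapse series of a linearly closing wound
#'
#' Frame `t` (0-based) has target background fraction
#' `wound_area_fraction * max(0, 1 - closure_rate * t)`; the texture
#' realization differs per frame.
#'
#' @param params a [synth_params] object (its `wound_area_fraction` is the
#'   initial wound size).
#' @param n_frames number of frames (>= 2).
#' @param closure_rate fraction of the initial area closed per frame (>= 0).
#' @return list of `ground_truth_pair`, one per frame.
#' @export
generate_wound_series <- function(params, n_frames, closure_rate) {
  stopifnot(inherits(params, "synth_params"))
  if (n_frames < 2) stopf("`n_frames` must be >= 2")
  if (closure_rate < 0) stopf("`closure_rate` must be >= 0")
  frame_seeds <- with_seed(params$rng_seed,
                           sample.int(.Machine$integer.max - 1L, n_frames))
  lapply(seq_len(n_frames), function(i) {
    t <- i - 1
    p <- params
    p$wound_area_fraction <- params$wound_area_fraction * max(0, 1 - closure_rate * t)
    p$rng_seed <- frame_seeds[i]
    generate_wound_image(p)
  })
}

#' Generate a synthetic scatter-assay image
#'
#' Non-scattered images contain a few large compact textured colonies;
#' scattered images contain many small dispersed blobs with a high
#' perimeter-to-area ratio and finer, stronger internal texture. Both
#' classes hit the same total cellular area, so only texture and dispersion
#' distinguish them.
#'
#' @param scattered logical: generate the scattered phenotype?
#' @param params a [synth_params] object (wound fields are ignored).
#' @param cell_area_fraction target fraction of cellular pixels.
#' @return a `ground_truth_pair` (`$mask` `TRUE` = background).
#' @export
generate_scatter_image <- function(scattered, params, cell_area_fraction = 0.35) {
  stopifnot(inherits(params, "synth_params"))
  h <- params$image_size[1]; w <- params$image_size[2]
  target_px <- cell_area_fraction * h * w
  with_seed(params$rng_seed, {
    yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
    cellular <- matrix(FALSE, h, w)
    paint_disk <- function(cy, cx, r) {
      nseg <- 32L
      prof <- edge_displacement(nseg, 0.15 * r)
      theta <- atan2(yy - cy, xx - cx)
      idx <- pmin(nseg, 1L + floor((theta + pi) / (2 * pi) * nseg))
      rad <- r + matrix(prof[idx], h, w)
      cellular <<- cellular | (sqrt((yy - cy)^2 + (xx - cx)^2) <= rad)
    }
    if (scattered) {
      r <- w / 28
      placed <- matrix(numeric(0), 0, 2)
      attempts <- 0L
      while (sum(cellular) < 0.97 * target_px && attempts < 4000L) {
        attempts <- attempts + 1L
        cy <- runif(1, 1.5 * r, h - 1.5 * r); cx <- runif(1, 1.5 * r, w - 1.5 * r)
        if (nrow(placed) > 0 && attempts < 2000L &&
            min(sqrt((placed[, 1] - cy)^2 + (placed[, 2] - cx)^2)) < 2.4 * r) next
        paint_disk(cy, cx, r)
        placed <- rbind(placed, c(cy, cx))
      }
      img <- paint_image(cellular, params, fine_sigma = 0.8, blob_sigma = 3,
                         strength = 1.6 * params$cell_texture_strength)
    } else {
      k <- 3L
      r <- sqrt(target_px / (k * pi))
      margin <- 1.15 * r
      base_pts <- rbind(c(0.3 * h, 0.3 * w), c(0.32 * h, 0.72 * w), c(0.72 * h, 0.5 * w))
      for (i in seq_len(k)) {
        cy <- clamp(base_pts[i, 1] + runif(1, -0.04, 0.04) * h, margin, h - margin)
        cx <- clamp(base_pts[i, 2] + runif(1, -0.04, 0.04) * w, margin, w - margin)
        paint_disk(cy, cx, r)
      }
      img <- paint_image(cellular, params, fine_sigma = 3, blob_sigma = 8,
                         strength = 0.9 * params$cell_texture_strength)
    }
    ground_truth_pair(
      calibrated_image(img, params$pixel_size_um, normalize = FALSE),
      segmentation_mask(!cellular, stage = "truth"))
  })
}

#' Write a set of ground-truth pairs with a manifest
#'
#' Writes each image (16-bit TIFF or 8-bit PNG by `format`), its truth mask
#' (8-bit PNG, background = 255), and a `manifest.csv` with columns
#' `filename, mask, pixel_size_um, seed` plus any extra metadata columns.
#'
#' @param pairs list of `ground_truth_pair`.
#' @param dir output directory (created if missing).
#' @param stem filename stem; files are `<stem>_<i>.<ext>`.
#' @param format `"tiff"` or `"png"`.
#' @param metadata optional data.frame with one row per pair.
#' @return the manifest as a data.frame, invisibly.
#' @export
write_fixture_set <- function(pairs, dir, stem = "synth", format = c("tiff", "png"),
                              metadata = NULL) {
  format <- match.arg(format)
  ext <- if (format == "tiff") "tif" else "png"
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(seq_along(pairs), function(i) {
    fn <- sprintf("%s_%03d.%s", stem, i, ext)
    mn <- sprintf("%s_%03d_mask.png", stem, i)
    write_calibrated_image(pairs[[i]]$image, file.path(dir, fn))
    write_mask(pairs[[i]]$mask, file.path(dir, mn))
    data.frame(filename = fn, mask = mn,
               pixel_size_um = pairs[[i]]$image$pixel_size_um)
  })
  manifest <- do.call(rbind, rows)
  if (!is.null(metadata)) manifest <- cbind(manifest, metadata)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
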