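# Wound-healing kinetics: per-frame background areas, normalized closure
# curves, linear healing-rate fits, and treatment comparisons.

#' Wound area over a time-lapse series
#'
#' The wound area of each frame is its background pixel count (times
#' `pixel_size_um^2` for square micrometres). The series is truncated at
#' the first frame with zero background area, operationalizing analysis
#' until first contact between the opposing wound borders. Areas are
#' normalized so the initial wound is 1.
#'
#' @param masks list of [segmentation_mask]s of equal shape, time order.
#' @param times numeric acquisition times (minutes), strictly increasing.
#' @param pixel_size_um optional pixel size; when given, `area_um2` is
#'   included.
#' @param well,treatment optional metadata strings carried through.
#' @return a `wound_series`: data.frame-like list with `times`, `areas`
#'   (pixels), `normalized_areas`, optional `areas_um2`, and metadata.
#' @export
wound_area_series <- function(masks, times, pixel_size_um = NULL,
                              well = NA_character_, treatment = NA_character_) {
  if (length(masks) < 2) stopf("need at least 2 frames")
  if (length(times) != length(masks)) stopf("times/masks length mismatch")
  if (any(diff(times) <= 0)) stopf("times must be strictly increasing")
  dims <- lapply(masks, dim)
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stopf("masks must share shape")
  areas <- vapply(masks, function(m) sum(unclass(m)), numeric(1))
  if (areas[1] == 0) stopf("first frame has zero background area; cannot normalize")
  zero <- which(areas == 0)
  keep <- if (length(zero)) seq_len(min(zero)) else seq_along(areas)
  areas <- areas[keep]; times <- times[keep]
  out <- list(times = times, areas = areas,
              normalized_areas = areas / areas[1],
              well = well, treatment = treatment)
  if (!is.null(pixel_size_um)) out$areas_um2 <- areas * pixel_size_um^2
  structure(out, class = "wound_series")
}

#' Linear healing-rate fit
#'
#' Ordinary least squares of normalized wound area on time, with Pearson's
#' correlation coefficient and its two-sided p-value (t distribution,
#' n - 2 df). A constant series is degenerate: slope 0, r reported as 0
#' with `degenerate = TRUE`.
#'
#' @param series a [wound_area_series] result.
#' @return a `healing_fit`: `slope` (normalized area per time unit),
#'   `intercept`, `pearson_r`, `p_value`, `n_points`, `degenerate`.
#' @export
fit_healing <- function(series) {
  stopifnot(inherits(series, "wound_series"))
  t <- series$times; a <- series$normalized_areas
  n <- length(t)
  if (n < 2) stopf("need at least 2 points")
  if (sd(a) < .Machine$double.eps^0.5) {
    return(structure(list(slope = 0, intercept = a[1], pearson_r = 0,
                          p_value = NA_real_, n_points = n, degenerate = TRUE),
                     class = "healing_fit"))
  }
  fit <- lm(a ~ t)
  r <- cor(t, a)
  p <- if (n >= 3) {
    tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
    2 * pt(-abs(tstat), df = n - 2)
  } else NA_real_
  structure(list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
                 pearson_r = r, p_value = p, n_points = n, degenerate = FALSE),
            class = "healing_fit")
}

#' Compare healing rates between two treatment arms
#'
#' The fold-change is the ratio of the median absolute healing slopes
#' (median across wells, robust to a failed well; means are reported too);
#' significance by the Wilcoxon rank sum test on the two slope samples.
#'
#' @param fits_treated,fits_untreated lists of `healing_fit`s (one per
#'   well).
#' @return list: `fold_change` (median-based), `fold_change_mean`,
#'   `p_value`, `slopes_treated`, `slopes_untreated`.
#' @export
compare_treatments <- function(fits_treated, fits_untreated) {
  if (length(fits_treated) < 1 || length(fits_untreated) < 1)
    stopf("need at least one fit per arm")
  st <- abs(vapply(fits_treated, function(f) f$slope, numeric(1)))
  su <- abs(vapply(fits_untreated, function(f) f$slope, numeric(1)))
  if (median(su) == 0) stopf("median untreated slope is zero; fold-change undefined")
  ranksum <- rank_sum_test(st, su)
  list(fold_change = median(st) / median(su),
       fold_change_mean = mean(st) / mean(su),
       p_value = ranksum$p_value,
       slopes_treated = st, slopes_untreated = su)
}

#' @export
print.healing_fit <- function(x, ...) {
  cat(sprintf("<healing_fit> slope %.4g per time unit, r = %.4f, p = %.3g, n = %d%s\n",
              x$slope, x$pearson_r, x$p_value, x$n_points,
              if (isTRUE(x$degenerate)) " (degenerate)" else ""))
  invisible(x)
}
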