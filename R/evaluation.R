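# Segmentation quality measures: pixel accuracy, pixel-level ROC of the
# confidence map (background = positive class), dataset-averaged ROC, and
# the paired significance tests used to compare methods.

#' Pixel accuracy of a segmentation
#'
#' Fraction of pixels whose predicted label matches the truth.
#'
#' @param pred,truth [segmentation_mask]s (or logical matrices) of equal
#'   shape.
#' @return accuracy in \[0, 1\].
#' @export
pixel_accuracy <- function(pred, truth) {
  if (!identical(dim(pred), dim(truth))) stopf("mask shapes differ")
  mean(unclass(pred) == unclass(truth))
}

#' Expand a patch confidence map to pixel resolution
#'
#' Nearest-neighbor expansion (each pixel inherits its patch's score),
#' cropped to the original image size — the resolution at which pixel-based
#' ROC rates are computed.
#'
#' @param confidence a `confidence_map`.
#' @param image_size optional (H, W); defaults to the map's recorded size.
#' @return numeric H x W matrix.
#' @export
expand_confidence <- function(confidence, image_size = NULL) {
  patch_size <- attr(confidence, "patch_size") %||% 20L
  image_size <- image_size %||% attr(confidence, "image_size")
  h <- image_size[1]; w <- image_size[2]
  pr <- pmin(((seq_len(h) - 1L) %/% patch_size) + 1L, nrow(confidence))
  pc <- pmin(((seq_len(w) - 1L) %/% patch_size) + 1L, ncol(confidence))
  unclass(confidence)[pr, pc, drop = FALSE]
}

#' Pixel-level ROC curve of a confidence map
#'
#' Background is the positive class: the true-positive rate is the fraction
#' of background pixels tagged background, the false-positive rate the
#' fraction of cellular pixels incorrectly tagged background. Every
#' distinct confidence value is swept as a threshold (`score >= t` tags
#' background); tied scores share one curve point. AUC is computed by the
#' trapezoid rule.
#'
#' @param confidence numeric vector/matrix of per-pixel confidences.
#' @param truth logical vector/matrix (`TRUE` = background), same length.
#' @return an `mcs_roc`: `fpr`, `tpr`, `thresholds` (decreasing; first
#'   point is the empty prediction at threshold `Inf`), `auc`.
#' @export
roc_curve <- function(confidence, truth) {
  sc <- as.vector(confidence); tr <- as.logical(truth)
  if (length(sc) != length(tr)) stopf("confidence/truth length mismatch")
  np <- sum(tr); nn <- sum(!tr)
  if (np == 0 || nn == 0) stopf("both classes must be present in truth")
  ord <- order(sc, decreasing = TRUE)
  sc <- sc[ord]; tr <- tr[ord]
  tp <- cumsum(tr); fp <- cumsum(!tr)
  last <- c(sc[-1] != sc[-length(sc)], TRUE)  # last index of each tie group
  tpr <- c(0, tp[last] / np)
  fpr <- c(0, fp[last] / nn)
  thresholds <- c(Inf, sc[last])
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(fpr = fpr, tpr = tpr, thresholds = thresholds, auc = auc),
            class = "mcs_roc")
}

# TPR of the ROC polyline at given FPR values: linear along diagonal/tie
# segments, and the top of any vertical run exactly at its FPR (the
# attainable operating envelope).
interpolate_roc <- function(curve, f) {
  fpr <- curve$fpr; tpr <- curve$tpr
  i <- findInterval(f, fpr)            # last point with fpr <= f
  out <- numeric(length(f))
  exact <- fpr[i] == f
  out[exact] <- tpr[i[exact]]          # duplicates sorted: last has max tpr
  ne <- which(!exact)
  if (length(ne)) {
    j <- i[ne] + 1L
    out[ne] <- tpr[i[ne]] + (f[ne] - fpr[i[ne]]) /
      (fpr[j] - fpr[i[ne]]) * (tpr[j] - tpr[i[ne]])
  }
  out
}

#' Vertically average ROC curves
#'
#' Interpolates each curve's TPR on a common FPR grid (0 to 1, step 0.01;
#' ties resolved to the highest attainable TPR) and averages pointwise;
#' AUC of the averaged curve by trapezoid.
#'
#' @param curves list of `mcs_roc` objects.
#' @return an `mcs_roc` on the common grid (no thresholds).
#' @export
average_rocs <- function(curves) {
  if (length(curves) < 1) stopf("need at least one curve")
  grid <- seq(0, 1, by = 0.01)
  tprs <- vapply(curves, function(cv) interpolate_roc(cv, grid),
                 numeric(length(grid)))
  tpr <- rowMeans(matrix(tprs, nrow = length(grid)))
  auc <- sum(diff(grid) * (head(tpr, -1) + tpr[-1]) / 2)
  structure(list(fpr = grid, tpr = tpr, thresholds = NULL, auc = auc),
            class = "mcs_roc")
}

#' @export
print.mcs_roc <- function(x, ...) {
  cat(sprintf("<roc> %d points, AUC = %.4f\n", length(x$fpr), x$auc))
  invisible(x)
}

#' Accuracy at a TPR-matched threshold
#'
#' Selects the threshold whose TPR is the smallest value >= the reference
#' TPR and returns pixel accuracy there — the device that puts two
#' confidence-producing methods on a like-for-like operating point.
#'
#' @param reference_tpr target true-positive (background) rate in \[0, 1\].
#' @param confidence per-pixel confidences.
#' @param truth logical truth (`TRUE` = background).
#' @return accuracy, with attributes `threshold`, `tpr` and `unreachable`
#'   (TRUE if no threshold attains the reference TPR).
#' @export
matched_threshold_accuracy <- function(reference_tpr, confidence, truth) {
  if (reference_tpr < 0 || reference_tpr > 1) stopf("reference_tpr must be in [0, 1]")
  roc <- roc_curve(confidence, truth)
  ok <- which(roc$tpr >= reference_tpr)
  unreachable <- length(ok) == 0
  if (unreachable) {
    warning("reference TPR unreachable; using the most permissive threshold")
    i <- length(roc$tpr)
  } else i <- ok[which.min(roc$tpr[ok])]
  thr <- roc$thresholds[i]
  pred <- as.vector(confidence) >= thr
  acc <- mean(pred == as.logical(truth))
  structure(acc, threshold = thr, tpr = roc$tpr[i], unreachable = unreachable)
}

#' Paired t-test on accuracy sequences
#'
#' Two-sided paired Student t-test. A degenerate case (zero variance of the
#' paired differences) reports p = 1.0 with `degenerate = TRUE` rather than
#' failing.
#'
#' @param acc_a,acc_b equal-length numeric vectors (>= 2 pairs).
#' @return list with `p_value`, `statistic`, `degenerate`.
#' @export
paired_accuracy_test <- function(acc_a, acc_b) {
  if (length(acc_a) != length(acc_b) || length(acc_a) < 2)
    stopf("need equal-length paired samples of size >= 2")
  d <- acc_a - acc_b
  if (sd(d) < .Machine$double.eps^0.5)
    return(list(p_value = 1.0, statistic = NA_real_, degenerate = TRUE))
  tt <- t.test(acc_a, acc_b, paired = TRUE)
  list(p_value = unname(tt$p.value), statistic = unname(tt$statistic),
       degenerate = FALSE)
}

#' Wilcoxon rank sum test
#'
#' Two-sided Mann-Whitney/Wilcoxon rank sum test. For combined sample sizes
#' up to 12 the null distribution of the rank sum is enumerated exactly
#' over all assignments of the observed (mid)ranks, which remains valid
#' under ties; above that a normal approximation with tie-corrected
#' variance is used.
#'
#' @param x,y numeric samples (both nonempty).
#' @return list with `p_value`, `statistic` (the Mann-Whitney U of `x`),
#'   `method`.
#' @export
rank_sum_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stopf("both samples must be nonempty")
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  u_obs <- w_obs - n1 * (n1 + 1) / 2
  if (n1 + n2 <= 12) {
    sums <- combn(r, n1, sum)
    p <- min(1, 2 * min(mean(sums <= w_obs), mean(sums >= w_obs)))
    method <- "exact enumeration"
  } else {
    n <- n1 + n2
    ties <- table(r)
    mu <- n1 * n2 / 2
    v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- (u_obs - mu) / sqrt(v)
    p <- 2 * pnorm(-abs(z))
    method <- "normal approximation (tie-corrected)"
  }
  list(p_value = p, statistic = u_obs, method = method)
}
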