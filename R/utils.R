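# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global random-number state so that seeded internal
#' draws never perturb a caller's random stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Gaussian smoothing; sigma = 0 returns the input untouched. Images smaller
# than the filter support are replicate-padded, blurred and cropped.
gaussian_smooth <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- 2L * as.integer(ceiling(3 * sigma)) + 1L  # gblur brush size
  h <- nrow(mat); w <- ncol(mat)
  if (h >= r && w >= r)
    return(EBImage::gblur(mat, sigma = sigma, boundary = "replicate"))
  pr <- max(0L, r - h); pc <- max(0L, r - w)
  ri <- c(rep(1L, pr), seq_len(h), rep(h, pr))
  ci <- c(rep(1L, pc), seq_len(w), rep(w, pc))
  big <- EBImage::gblur(mat[ri, ci, drop = FALSE], sigma = sigma,
                        boundary = "replicate")
  big[pr + seq_len(h), pc + seq_len(w), drop = FALSE]
}

# Recursively drop S3 classes so plain structures serialize to JSON.
strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else unclass(x)
}

# 1-D Gaussian smoothing with reflected ends.
gaussian_smooth_1d <- function(x, sigma) {
  if (sigma <= 0) return(x)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2)); k <- k / sum(k)
  n <- length(x)
  pad <- c(x[pmin(n, r:1 + 1L)], x, x[pmax(1L, n - (1:r))])
  as.numeric(stats::filter(pad, k, sides = 2))[(r + 1L):(r + n)]
}

# Central-difference gradient on the full image; one-sided at borders.
# Returns list(gx, gy, mag) with gy along rows (image y) and gx along columns.
image_gradient <- function(mat) {
  h <- nrow(mat); w <- ncol(mat)
  gy <- matrix(0, h, w); gx <- matrix(0, h, w)
  if (h >= 3) gy[2:(h - 1), ] <- (mat[3:h, ] - mat[1:(h - 2), ]) / 2
  if (h >= 2) { gy[1, ] <- mat[2, ] - mat[1, ]; gy[h, ] <- mat[h, ] - mat[h - 1, ] }
  if (w >= 3) gx[, 2:(w - 1)] <- (mat[, 3:w] - mat[, 1:(w - 2)]) / 2
  if (w >= 2) { gx[, 1] <- mat[, 2] - mat[, 1]; gx[, w] <- mat[, w] - mat[, w - 1] }
  list(gx = gx, gy = gy, mag = sqrt(gx^2 + gy^2))
}

# 4-neighbour discrete Laplacian with replicated borders.
image_laplacian <- function(mat) {
  h <- nrow(mat); w <- ncol(mat)
  up <- mat[c(1, seq_len(h - 1)), , drop = FALSE]
  dn <- mat[c(seq_len(h - 1) + 1, h), , drop = FALSE]
  lf <- mat[, c(1, seq_len(w - 1)), drop = FALSE]
  rt <- mat[, c(seq_len(w - 1) + 1, w), drop = FALSE]
  up + dn + lf + rt - 4 * mat
}

#' Otsu threshold over an arbitrary real-valued sample
#'
#' Maximizes between-class variance over candidate cut points placed between
#' the distinct sorted values. Works on signed data such as SVM confidence
#' scores (unlike fixed-range image thresholding).
#' @param x numeric vector with at least two distinct values.
#' @return a threshold `t`; the two classes are `x <= t` and `x > t`.
#' @keywords internal
otsu_threshold <- function(x) {
  u <- sort(unique(x))
  if (length(u) < 2) return(u[1])
  cnt <- tabulate(match(x, u))
  n <- length(x)
  cn <- cumsum(cnt)                  # observations <= u[k]
  cs <- cumsum(cnt * u)
  k <- seq_len(length(u) - 1L)       # cut between u[k] and u[k+1]
  wb <- cn[k] / n
  mlo <- cs[k] / cn[k]
  mhi <- (cs[length(u)] - cs[k]) / (n - cn[k])
  between <- wb * (1 - wb) * (mlo - mhi)^2
  best <- which.max(between)
  (u[best] + u[best + 1L]) / 2
}

# Bilinear upsampling of a patch-grid array to pixel resolution. Values are
# anchored at patch centers; pixels outside the outermost centers clamp to
# the nearest center (constant extrapolation).
upsample_bilinear <- function(grid_vals, patch_size, out_h, out_w) {
  nr <- nrow(grid_vals); nc <- ncol(grid_vals)
  centers_r <- (seq_len(nr) - 0.5) * patch_size
  centers_c <- (seq_len(nc) - 0.5) * patch_size
  py <- seq_len(out_h) - 0.5
  px <- seq_len(out_w) - 0.5
  interp_idx <- function(p, centers) {
    # returns lower index, and fractional weight of upper index
    i <- findInterval(p, centers)
    i0 <- clamp(i, 1L, length(centers) - 1L)
    if (length(centers) == 1L) return(list(i0 = rep(1L, length(p)), w = rep(0, length(p))))
    w <- (p - centers[i0]) / (centers[i0 + 1L] - centers[i0])
    list(i0 = i0, w = clamp(w, 0, 1))
  }
  ry <- interp_idx(py, centers_r)
  rx <- interp_idx(px, centers_c)
  a00 <- grid_vals[ry$i0, rx$i0, drop = FALSE]
  a10 <- grid_vals[clamp(ry$i0 + 1L, 1L, nr), rx$i0, drop = FALSE]
  a01 <- grid_vals[ry$i0, clamp(rx$i0 + 1L, 1L, nc), drop = FALSE]
  a11 <- grid_vals[clamp(ry$i0 + 1L, 1L, nr), clamp(rx$i0 + 1L, 1L, nc), drop = FALSE]
  wy <- matrix(ry$w, out_h, out_w)
  wx <- matrix(rx$w, out_h, out_w, byrow = TRUE)
  a00 * (1 - wy) * (1 - wx) + a10 * wy * (1 - wx) + a01 * (1 - wy) * wx + a11 * wy * wx
}

# Area of the convex hull of a set of 2-d points (shoelace on chull order).
convex_hull_area <- function(pts) {
  if (nrow(pts) < 3) return(0)
  h <- chull(pts)
  p <- pts[h, , drop = FALSE]
  x <- p[, 1]; y <- p[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
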