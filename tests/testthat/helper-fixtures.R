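# Shared fixtures and independent oracles. Heavy objects (trained models)
# are memoised so the suite trains each model once.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Training set for wound segmentation: five images spanning wide to narrow
# wounds so both classifier stages see thin wound regions.
wound_training_pairs <- function() memo("wound_train", {
  fracs <- c(0.35, 0.30, 0.25, 0.18, 0.10)
  lapply(1:5, function(i) generate_wound_image(
    synth_params(rng_seed = 100L + i, wound_area_fraction = fracs[i])))
})

wound_model <- function() memo("wound_model", {
  train_multicellseg(wound_training_pairs(), seed = 1L)
})

# Finer 10-px patches for the time-lapse kinetics study, where boundary
# tracking resolution matters more than per-patch context.
wound_model_fine <- function() memo("wound_model_fine", {
  train_multicellseg(wound_training_pairs(), seed = 1L, patch_size = 10L)
})

scatter_params <- function(seed) {
  synth_params(image_size = c(192L, 192L), pixel_size_um = 5, rng_seed = seed)
}

scatter_seg_model <- function() memo("scatter_model", {
  train <- c(lapply(1:2, function(i) generate_scatter_image(FALSE, scatter_params(9000L + i))),
             lapply(1:2, function(i) generate_scatter_image(TRUE, scatter_params(9100L + i))))
  train_multicellseg(train, seed = 1L)
})

random_image <- function(seed, h = 16L, w = 16L) {
  calibrated_image(matrix(with_seed_test(seed, runif(h * w)), h, w),
                   pixel_size_um = 1, normalize = FALSE)
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# ---- independent oracles -------------------------------------------------

# Brute-force per-pixel LBP (riu2, P = 8, R = 1): straightforward scalar
# loops, independent of the package's vectorized implementation.
oracle_lbp_descriptor <- function(m, cellular = NULL) {
  h <- nrow(m); w <- ncol(m)
  if (is.null(cellular)) cellular <- matrix(TRUE, h, w)
  angles <- 2 * pi * (0:7) / 8
  counts <- numeric(10)
  for (r in 2:(h - 1)) for (c in 2:(w - 1)) {
    if (!cellular[r, c]) next
    bits <- integer(8)
    for (k in 1:8) {
      # same circular geometry: E, NE, N, NW, W, SW, S, SE
      dr <- -sin(angles[k]); dc <- cos(angles[k])
      rr <- r + dr; cc <- c + dc
      val <- if (abs(rr - round(rr)) < 1e-9 && abs(cc - round(cc)) < 1e-9) {
        m[round(rr), round(cc)]
      } else {
        r0 <- floor(rr); c0 <- floor(cc); fr <- rr - r0; fc <- cc - c0
        (1 - fr) * (1 - fc) * m[r0, c0] + fr * (1 - fc) * m[r0 + 1, c0] +
          (1 - fr) * fc * m[r0, c0 + 1] + fr * fc * m[r0 + 1, c0 + 1]
      }
      bits[k] <- as.integer(val >= m[r, c])
    }
    trans <- sum(bits != c(bits[-1], bits[1]))
    code <- if (trans <= 2) sum(bits) else 9L
    counts[code + 1] <- counts[code + 1] + 1
  }
  counts / sum(counts)
}

# Exhaustive minimum of a small binary energy.
oracle_energy_min <- function(energy) {
  h <- nrow(energy$cost_cell); w <- ncol(energy$cost_cell)
  n <- h * w
  best <- Inf
  for (code in 0:(2^n - 1)) {
    lab <- matrix(as.logical(bitwAnd(bitwShiftR(code, 0:(n - 1)), 1L)), h, w)
    e <- labeling_energy(energy, lab)
    if (e < best) best <- e
  }
  best
}

random_small_energy <- function(seed, h, w) {
  with_seed_test(seed, segmentation_energy(
    matrix(runif(h * w, 0, 2), h), matrix(runif(h * w, 0, 2), h),
    matrix(runif(h * (w - 1)), h), matrix(runif((h - 1) * w), h - 1)))
}

# Recursive flood fill, independent of the package BFS.
oracle_component_count <- function(labels, connectivity = 4L) {
  nr <- nrow(labels); nc <- ncol(labels)
  seen <- matrix(FALSE, nr, nc)
  nbr <- if (connectivity == 4L) list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  fill <- function(r, c) {
    stack <- list(c(r, c)); seen[r, c] <<- TRUE
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      for (d in nbr) {
        rr <- p[1] + d[1]; cc <- p[2] + d[2]
        if (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
            labels[rr, cc] && !seen[rr, cc]) {
          seen[rr, cc] <<- TRUE
          stack[[length(stack) + 1]] <- c(rr, cc)
        }
      }
    }
  }
  count <- 0L
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (labels[r, c] && !seen[r, c]) { count <- count + 1L; fill(r, c) }
  }
  count
}

# Brute-force Otsu: maximize between-class variance over every midpoint cut.
oracle_otsu <- function(x) {
  v <- sort(unique(x))
  cuts <- (v[-length(v)] + v[-1]) / 2
  best <- -Inf; best_cut <- cuts[1]
  for (ct in cuts) {
    lo <- x[x <= ct]; hi <- x[x > ct]
    wb <- length(lo) / length(x)
    s <- wb * (1 - wb) * (mean(lo) - mean(hi))^2
    if (s > best) { best <- s; best_cut <- ct }
  }
  best_cut
}
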