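# Region-level reclassification: connected components of background-labeled
# patches are re-examined by a separate linear classifier that sees pooled,
# region-scale texture, and false wound regions are vetoed.

#' Connected components of background-labeled patches
#'
#' @param patch_labels logical matrix of patch labels (`TRUE` = background).
#' @param connectivity 4 (default) or 8; 4-connectivity avoids merging
#'   diagonal speckle into wound regions.
#' @return list of `region_component`s ordered by (min row, min col); each
#'   has `patches` (n x 2 matrix of 0-based (r, c)) and `area` (patch
#'   count).
#' @export
extract_background_components <- function(patch_labels, connectivity = 4L) {
  if (!connectivity %in% c(4L, 8L)) stopf("connectivity must be 4 or 8")
  nr <- nrow(patch_labels); nc <- ncol(patch_labels)
  lab <- matrix(0L, nr, nc)
  nbr <- if (connectivity == 4L)
    cbind(c(-1L, 1L, 0L, 0L), c(0L, 0L, -1L, 1L))
  else
    cbind(rep(c(-1L, 0L, 1L), 3L), rep(c(-1L, 0L, 1L), each = 3L))[-5L, ]
  comp_id <- 0L
  comps <- list()
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (!patch_labels[r, c] || lab[r, c] > 0L) next
    comp_id <- comp_id + 1L
    queue <- matrix(c(r, c), 1L)
    lab[r, c] <- comp_id
    members <- matrix(integer(0), 0L, 2L)
    while (nrow(queue) > 0L) {
      cur <- queue[1L, ]; queue <- queue[-1L, , drop = FALSE]
      members <- rbind(members, cur)
      for (k in seq_len(nrow(nbr))) {
        rr <- cur[1L] + nbr[k, 1L]; cc <- cur[2L] + nbr[k, 2L]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc &&
            patch_labels[rr, cc] && lab[rr, cc] == 0L) {
          lab[rr, cc] <- comp_id
          queue <- rbind(queue, c(rr, cc))
        }
      }
    }
    comps[[comp_id]] <- structure(
      list(patches = unname(members) - 1L, area = nrow(members)),
      class = "region_component")
  }
  ord <- order(vapply(comps, function(cp) min(cp$patches[, 1]), numeric(1)),
               vapply(comps, function(cp) min(cp$patches[, 2]), numeric(1)))
  comps[ord]
}

# Fraction of grid cells inside the convex hull of the member cell centers;
# solidity = area / that count. Degenerate hulls (area 0) give solidity 1.
component_solidity <- function(component, n_rows, n_cols) {
  pts <- component$patches + 0.5  # cell centers
  if (nrow(pts) < 3 || convex_hull_area(pts) < 1e-9) return(1)
  hull <- pts[chull(pts), , drop = FALSE]
  centers <- cbind(rep(seq_len(n_rows) - 0.5, each = n_cols),
                   rep(seq_len(n_cols) - 0.5, n_rows))
  nh <- nrow(hull)
  inside <- rep(TRUE, nrow(centers))
  # chull returns clockwise order; a point is inside iff it is on the same
  # side of every edge.
  for (i in seq_len(nh)) {
    a <- hull[i, ]; b <- hull[if (i == nh) 1L else i + 1L, ]
    cross <- (b[1] - a[1]) * (centers[, 2] - a[2]) -
             (b[2] - a[2]) * (centers[, 1] - a[1])
    inside <- inside & (cross <= 1e-9)
  }
  hull_cells <- max(sum(inside), component$area)
  component$area / hull_cells
}

#' Region-scale feature vector of a background component
#'
#' Pools texture over the whole component — the advantage of the region
#' stage is exactly that a grouped region carries far more textural
#' information than any single patch. The vector is
#' `[log(area), mean confidence, min confidence, fraction of member patches
#' above the image's median background-patch confidence, pooled 16-bin
#' gradient-magnitude histogram, pooled multi-scale standard deviations,
#' solidity on the patch grid]`.
#'
#' @param image the [calibrated_image] the labels came from.
#' @param confidence the `confidence_map` of the image.
#' @param component a `region_component`.
#' @param patch_labels the patch labeling the component was extracted from.
#' @param config the [patch_feature_config] in use.
#' @param context optional precomputed [region_feature_context] for the
#'   image (avoids repeating image-wide filtering per component).
#' @return numeric feature vector.
#' @export
compute_region_features <- function(image, confidence, component, patch_labels,
                                    config = patch_feature_config(),
                                    context = NULL) {
  if (is.null(context))
    context <- region_feature_context(image,
                                      attr(confidence, "patch_size") %||% 20L,
                                      config)
  grid <- context$grid
  idx <- component$patches
  conf_vals <- confidence[idx + 1L]
  bg_scores <- confidence[patch_labels]
  med_bg <- if (length(bg_scores)) median(bg_scores) else 0
  lin <- component_pixel_support(component, grid)
  pooled_grad <- fixed_histogram(context$gmag[lin], 0, sqrt(2) / 2, 16L)
  pooled_sd <- vapply(context$smoothed, function(sm) sd(sm[lin]), numeric(1))
  c(log(component$area),
    mean(conf_vals), min(conf_vals),
    mean(conf_vals > med_bg),
    pooled_grad, pooled_sd,
    component_solidity(component, nrow(patch_labels), ncol(patch_labels)))
}

#' Precompute image-wide quantities for region features
#'
#' @param image a [calibrated_image].
#' @param patch_size patch side in pixels.
#' @param config a [patch_feature_config].
#' @return list with the patch grid, gradient-magnitude image and the
#'   Gaussian-smoothed images at the configured scales.
#' @export
region_feature_context <- function(image, patch_size = 20L,
                                   config = patch_feature_config()) {
  grid <- build_patch_grid(image, patch_size)
  list(grid = grid,
       gmag = image_gradient(grid$padded)$mag,
       smoothed = lapply(config$variance_sigmas,
                         function(sg) gaussian_smooth(grid$padded, sg)))
}

component_pixel_support <- function(component, grid) {
  # 1-based pixel (row, col) pairs on the padded image
  idx <- component$patches
  out <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    w <- patch_window(grid, idx[i, 1], idx[i, 2])
    out[[i]] <- cbind(rep(w$rows, times = length(w$cols)),
                      rep(w$cols, each = length(w$rows)))
  }
  do.call(rbind, out)
}

# Plant a connected fake background component of `size` patches starting
# from a cellular seed patch — used to synthesize hard negatives when the
# cascade makes no natural mistakes on the training fixtures.
plant_component <- function(cellular_patches, size, nr, nc) {
  seedp <- cellular_patches[sample.int(nrow(cellular_patches), 1L), ]
  members <- matrix(seedp, 1L)
  while (nrow(members) < size) {
    base <- members[sample.int(nrow(members), 1L), ]
    step <- rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))[sample.int(4L, 1L), ]
    cand <- base + step
    if (cand[1] < 0 || cand[1] >= nr || cand[2] < 0 || cand[2] >= nc) next
    if (any(members[, 1] == cand[1] & members[, 2] == cand[2])) next
    members <- rbind(members, cand)
  }
  structure(list(patches = unname(members), area = nrow(members)),
            class = "region_component")
}

#' Train the region classifier
#'
#' Runs the cascade and automatic threshold on the training images,
#' extracts background components, labels each true-background iff more
#' than half of its pixel support is background in the truth mask, and fits
#' a linear SVM on region features. When the cascade makes no natural
#' mistakes on the training images, hard negatives are synthesized by
#' planting false background components inside cellular regions (seeded,
#' deterministic) — otherwise the veto stage would be untrainable.
#'
#' @param training_pairs list of `ground_truth_pair`.
#' @param cascade a trained `cascade_model`.
#' @param seed integer seed (fold split and hard-negative planting).
#' @param C linear SVM cost.
#' @param threshold_method passed to [threshold_confidence].
#' @return a `region_model`.
#' @export
train_region_classifier <- function(training_pairs, cascade, seed = 1L, C = 1,
                                    threshold_method = "otsu") {
  config <- cascade$meta$config
  feats <- list(); labs <- logical(0)
  with_seed(seed, {
    for (pair in training_pairs) {
      grid <- build_patch_grid(pair$image, cascade$meta$patch_size)
      pf <- extract_feature_sets(pair$image, grid, config)
      conf <- score_patches(cascade, pf)
      plab <- threshold_confidence(conf, threshold_method)
      comps <- extract_background_components(plab)
      ctx <- region_feature_context(pair$image, cascade$meta$patch_size, config)
      truth_pad <- patch_labels_from_mask(pair$mask, grid, 0.5)
      truth_grid <- matrix(truth_pad, grid$n_rows, grid$n_cols, byrow = TRUE)
      for (cp in comps) {
        sup <- component_pixel_support(cp, grid)
        reflect <- function(n, target) if (target == n) seq_len(n) else
          c(seq_len(n), seq(n - 1, by = -1, length.out = target - n))
        pm <- pair$mask[reflect(nrow(pair$mask), nrow(grid$padded)),
                        reflect(ncol(pair$mask), ncol(grid$padded)), drop = FALSE]
        labs <- c(labs, mean(pm[sup]) > 0.5)
        feats[[length(feats) + 1L]] <-
          compute_region_features(pair$image, conf, cp, plab, config, ctx)
      }
      if (!any(!labs)) {
        # synthesize hard negatives inside truly cellular areas
        cell_patches <- which(!truth_grid, arr.ind = TRUE) - 1L
        if (nrow(cell_patches) > 0) {
          n_plant <- 3L
          for (j in seq_len(n_plant)) {
            cp <- plant_component(cell_patches, sample(1:4, 1L),
                                  grid$n_rows, grid$n_cols)
            labs <- c(labs, FALSE)
            feats[[length(feats) + 1L]] <-
              compute_region_features(pair$image, conf, cp, plab, config, ctx)
          }
        }
      }
    }
  })
  if (length(unique(labs)) < 2)
    stopf("region training found a single component class even after hard-negative synthesis")
  X <- do.call(rbind, feats)
  std <- standardizer(X)
  hp <- fit_linear_hyperplane(apply_standardizer(X, std), labs, C = C)
  structure(list(hp = hp, std = std,
                 meta = list(seed = as.integer(seed), C = C,
                             threshold_method = threshold_method,
                             n_features = ncol(X), version = "1")),
            class = "region_model")
}

# Signed distance of region feature vectors to the region hyperplane;
# positive = true background.
score_regions <- function(model, feature_matrix) {
  hyperplane_distance(apply_standardizer(feature_matrix, model$std), model$hp)
}

#' Veto false background components
#'
#' Components the region classifier scores as cellular are relabeled
#' cellular; all other labels are unchanged. The operation is monotone: it
#' never creates new background patches.
#'
#' @param model a `region_model`.
#' @param components list of `region_component`s.
#' @param patch_labels logical patch-label matrix the components came from.
#' @param image,confidence the source image and its `confidence_map`
#'   (needed to compute region features).
#' @param config the [patch_feature_config] in use.
#' @return refined logical patch-label matrix, with a `decisions` attribute
#'   (data.frame: component id, area, score, kept).
#' @export
filter_regions <- function(model, components, patch_labels, image, confidence,
                           config = patch_feature_config()) {
  out <- patch_labels
  if (length(components) == 0) {
    attr(out, "decisions") <- data.frame(id = integer(0), area = integer(0),
                                         score = numeric(0), kept = logical(0))
    return(out)
  }
  ctx <- region_feature_context(image, attr(confidence, "patch_size") %||% 20L,
                                config)
  X <- do.call(rbind, lapply(components, function(cp)
    compute_region_features(image, confidence, cp, patch_labels, config, ctx)))
  sc <- score_regions(model, X)
  kept <- sc > 0
  for (i in seq_along(components)) {
    if (!kept[i]) out[components[[i]]$patches + 1L] <- FALSE
  }
  attr(out, "decisions") <- data.frame(
    id = seq_along(components),
    area = vapply(components, function(cp) cp$area, integer(1)),
    score = sc, kept = kept)
  out
}

#' @rdname save_cascade
#' @export
save_region_model <- function(model, path) {
  jsonlite::write_json(strip_classes(model), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname save_cascade
#' @export
load_region_model <- function(path) {
  structure(jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE),
            class = "region_model")
}
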