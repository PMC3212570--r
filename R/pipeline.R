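# End-to-end training and segmentation: cascade -> automatic threshold ->
# region veto -> graph-cut refinement.

#' Train the full segmentation model
#'
#' Fits the patch-classification cascade and then the region classifier on
#' the same training set.
#'
#' @param training_pairs list of `ground_truth_pair`.
#' @param patch_size patch side in pixels.
#' @param seed integer seed (cross-fitting split, hard-negative planting).
#' @param config a [patch_feature_config].
#' @param C linear SVM cost.
#' @param threshold_method automatic threshold for the patch stage.
#' @return a `multicellseg_model` with fields `cascade` and `region`.
#' @export
train_multicellseg <- function(training_pairs, patch_size = 20L, seed = 1L,
                               config = patch_feature_config(), C = 1,
                               threshold_method = "otsu") {
  cascade <- train_cascade(training_pairs, patch_size = patch_size, seed = seed,
                           config = config, C = C)
  region <- train_region_classifier(training_pairs, cascade, seed = seed, C = C,
                                    threshold_method = threshold_method)
  structure(list(cascade = cascade, region = region,
                 meta = list(threshold_method = threshold_method)),
            class = "multicellseg_model")
}

# Patch labels -> pixel mask at the original image size.
patch_labels_to_mask <- function(patch_labels, patch_size, image_size, stage) {
  h <- image_size[1]; w <- image_size[2]
  pr <- pmin(((seq_len(h) - 1L) %/% patch_size) + 1L, nrow(patch_labels))
  pc <- pmin(((seq_len(w) - 1L) %/% patch_size) + 1L, ncol(patch_labels))
  segmentation_mask(patch_labels[pr, pc, drop = FALSE], stage = stage)
}

#' Segment an image with a trained model
#'
#' Runs the full pipeline and returns every stage: the confidence map, the
#' thresholded patch labeling, the region-filtered labeling, and the final
#' graph-cut mask.
#'
#' @param model a `multicellseg_model`.
#' @param image a [calibrated_image].
#' @param lambda,logistic_scale,seed_erosion_px graph-cut energy settings
#'   (see [build_energy]).
#' @param connectivity patch connectivity for region extraction.
#' @return a `multicellseg_result`: list with `confidence`, `patch_labels`,
#'   `region_labels`, `mask_patch`, `mask_region`, `mask_final`,
#'   `region_decisions`.
#' @export
segment_image <- function(model, image, lambda = 1.0, logistic_scale = 1.0,
                          seed_erosion_px = NULL, connectivity = 4L) {
  stopifnot(inherits(model, "multicellseg_model"),
            inherits(image, "calibrated_image"))
  patch_size <- model$cascade$meta$patch_size
  config <- model$cascade$meta$config
  grid <- build_patch_grid(image, patch_size)
  feats <- extract_feature_sets(image, grid, config)
  conf <- score_patches(model$cascade, feats)
  plab <- threshold_confidence(conf, model$meta$threshold_method %||% "otsu")
  comps <- extract_background_components(plab, connectivity)
  rlab <- filter_regions(model$region, comps, plab, image, conf, config)
  energy <- build_energy(image, conf, rlab, lambda = lambda,
                         logistic_scale = logistic_scale,
                         seed_erosion_px = seed_erosion_px)
  final <- min_cut_segment(energy, stage = "final")
  img_size <- dim(image$intensities)
  structure(list(
    confidence = conf,
    patch_labels = plab,
    region_labels = rlab,
    mask_patch = patch_labels_to_mask(plab, patch_size, img_size, "patch"),
    mask_region = patch_labels_to_mask(rlab, patch_size, img_size,
                                       "region-filtered"),
    mask_final = final,
    region_decisions = attr(rlab, "decisions")),
    class = "multicellseg_result")
}

#' Save / load a full segmentation model
#'
#' @param model a `multicellseg_model`.
#' @param path JSON file path.
#' @return `load_multicellseg` returns the model.
#' @export
save_multicellseg <- function(model, path) {
  obj <- list(cascade = strip_classes(model$cascade),
              region = strip_classes(model$region), meta = model$meta)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_multicellseg
#' @export
load_multicellseg <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  cascade <- raw$cascade
  cascade$meta$config <- do.call(patch_feature_config, cascade$meta$config)
  structure(list(cascade = structure(cascade, class = "cascade_model"),
                 region = structure(raw$region, class = "region_model"),
                 meta = raw$meta),
            class = "multicellseg_model")
}

#' Evaluate a model on ground-truth pairs
#'
#' Per image: patch-stage and final pixel accuracy and the pixel-level AUC
#' of the confidence map; returns one row per image plus the ROC curves,
#' ready for dataset-level averaging and significance testing.
#'
#' @param model a `multicellseg_model`.
#' @param pairs list of `ground_truth_pair`.
#' @param ... passed to [segment_image].
#' @return list: `per_image` data.frame (`accuracy_patch`,
#'   `accuracy_region`, `accuracy_final`, `auc`), `rocs` (list of
#'   `mcs_roc`), `mean_roc`.
#' @export
evaluate_model <- function(model, pairs, ...) {
  rows <- list(); rocs <- list()
  for (i in seq_along(pairs)) {
    pr <- pairs[[i]]
    res <- segment_image(model, pr$image, ...)
    conf_px <- expand_confidence(res$confidence, dim(pr$image$intensities))
    roc <- roc_curve(conf_px, pr$mask)
    rocs[[i]] <- roc
    rows[[i]] <- data.frame(
      image = i,
      accuracy_patch = pixel_accuracy(res$mask_patch, pr$mask),
      accuracy_region = pixel_accuracy(res$mask_region, pr$mask),
      accuracy_final = pixel_accuracy(res$mask_final, pr$mask),
      auc = roc$auc)
  }
  list(per_image = do.call(rbind, rows), rocs = rocs,
       mean_roc = average_rocs(rocs))
}
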