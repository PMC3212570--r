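# Linear SVM fitting and the two-stage (five feature-set SVMs + combiner)
# patch classification cascade. Models are stored as plain hyperplanes
# (weights, bias, standardization) so they serialize exactly and scoring
# never needs the fitting library.

# Fit a linear SVM and return the hyperplane with sign normalized so that
# positive decision values correspond to `positive == TRUE` rows.
fit_linear_hyperplane <- function(X, positive, C = 1, balanced = TRUE) {
  if (length(unique(positive)) < 2)
    stopf("training data contains a single class; both cellular and background examples are required")
  y <- factor(ifelse(positive, "pos", "neg"))
  cw <- if (balanced) {
    tab <- table(y)
    stats::setNames(as.numeric(sum(tab) / (2 * tab)), names(tab))
  } else NULL
  fit <- e1071::svm(x = X, y = y, kernel = "linear", cost = C, scale = FALSE,
                    class.weights = cw)
  w <- drop(t(fit$coefs) %*% fit$SV)
  b <- -fit$rho
  dec <- drop(X %*% w) + b
  if (mean(dec[positive]) < mean(dec[!positive])) { w <- -w; b <- -b }
  list(w = as.numeric(w), b = as.numeric(b))
}

standardizer <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[!is.finite(scale) | scale < 1e-8] <- 1
  list(center = as.numeric(center), scale = as.numeric(scale))
}

apply_standardizer <- function(X, std) {
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

# Signed Euclidean distance of standardized rows to the hyperplane.
hyperplane_distance <- function(X, hp) {
  nrm <- sqrt(sum(hp$w^2))
  if (nrm < 1e-12) stopf("degenerate hyperplane with zero weight vector")
  (drop(X %*% hp$w) + hp$b) / nrm
}

# Patch truth labels from a pixel mask: background iff > `majority` of the
# patch's (padded) pixels are background.
patch_labels_from_mask <- function(mask, grid, majority = 0.5) {
  reflect_idx <- function(n, target) {
    if (target == n) seq_len(n) else c(seq_len(n), seq(n - 1, by = -1,
                                                       length.out = target - n))
  }
  pm <- mask[reflect_idx(nrow(mask), nrow(grid$padded)),
             reflect_idx(ncol(mask), ncol(grid$padded)), drop = FALSE]
  out <- logical(grid$n_rows * grid$n_cols)
  i <- 0L
  for (r in 0:(grid$n_rows - 1L)) for (c in 0:(grid$n_cols - 1L)) {
    i <- i + 1L
    w <- patch_window(grid, r, c)
    out[i] <- mean(pm[w$rows, w$cols]) > majority
  }
  out
}

cascade_feature_matrices <- function(features) {
  lapply(c("F1", "F2", "F3", "F4", "F5"), function(nm) features[[nm]])
}

stage_one_scores <- function(model, features) {
  mats <- cascade_feature_matrices(features)
  if (length(mats) != length(model$stage_one))
    stopf("model/feature incompatibility: %d feature sets vs %d stage-one SVMs",
          length(mats), length(model$stage_one))
  scores <- mapply(function(mat, st) {
    if (ncol(mat) != length(st$hp$w))
      stopf("feature length mismatch: set has %d columns, model expects %d",
            ncol(mat), length(st$hp$w))
    hyperplane_distance(apply_standardizer(mat, st$std), st$hp)
  }, mats, model$stage_one)
  matrix(scores, ncol = length(model$stage_one))
}

#' Train the patch-classification SVM cascade
#'
#' Stage one fits one linear SVM per feature set (five in the default
#' configuration); the combiner is a linear SVM over the five stage-one
#' confidence scores. Combiner training inputs are produced by 2-fold
#' cross-fitting (each half is scored by stage-one SVMs trained on the
#' other half) so the stacking step never sees optimistically in-sample
#' scores. Class weights are balanced because wound images are mostly
#' cellular. A patch's training label is background iff more than half of
#' its pixels are background in the truth mask.
#'
#' @param training_pairs list of `ground_truth_pair` (image + truth mask).
#' @param patch_size patch side in pixels (default 20).
#' @param seed integer seed controlling the cross-fitting split.
#' @param config a [patch_feature_config].
#' @param C soft-margin cost of every linear SVM.
#' @param majority fraction of background pixels above which a patch is
#'   labeled background.
#' @return a `cascade_model`.
#' @export
train_cascade <- function(training_pairs, patch_size = 20L, seed = 1L,
                          config = patch_feature_config(), C = 1,
                          majority = 0.5) {
  sets <- vector("list", 5L)
  labels <- logical(0)
  for (pair in training_pairs) {
    grid <- build_patch_grid(pair$image, patch_size)
    feats <- extract_feature_sets(pair$image, grid, config)
    mats <- cascade_feature_matrices(feats)
    for (k in seq_len(5)) sets[[k]] <- rbind(sets[[k]], mats[[k]])
    labels <- c(labels, patch_labels_from_mask(pair$mask, grid, majority))
  }
  if (length(unique(labels)) < 2)
    stopf("training images yield a single patch class; include images with both cellular and background patches")

  stds <- lapply(sets, standardizer)
  stage_one <- lapply(seq_len(5), function(k) {
    Z <- apply_standardizer(sets[[k]], stds[[k]])
    list(hp = fit_linear_hyperplane(Z, labels, C = C), std = stds[[k]])
  })

  # Out-of-fold stage-one scores for the combiner (2-fold cross-fitting).
  n <- length(labels)
  fold <- with_seed(seed, sample(rep(1:2, length.out = n)))
  oof <- matrix(NA_real_, n, 5L)
  for (f in 1:2) {
    tr <- fold != f; te <- fold == f
    if (length(unique(labels[tr])) < 2)
      stopf("cross-fitting fold lost a class; provide more balanced training data")
    for (k in seq_len(5)) {
      std_f <- standardizer(sets[[k]][tr, , drop = FALSE])
      hp_f <- fit_linear_hyperplane(
        apply_standardizer(sets[[k]][tr, , drop = FALSE], std_f), labels[tr], C = C)
      oof[te, k] <- hyperplane_distance(
        apply_standardizer(sets[[k]][te, , drop = FALSE], std_f), hp_f)
    }
  }
  comb_std <- standardizer(oof)
  combiner <- list(hp = fit_linear_hyperplane(apply_standardizer(oof, comb_std),
                                              labels, C = C),
                   std = comb_std)

  structure(list(stage_one = stage_one, combiner = combiner,
                 meta = list(patch_size = as.integer(patch_size),
                             config = config, seed = as.integer(seed), C = C,
                             majority = majority, version = "1")),
            class = "cascade_model")
}

#' Score patches with a trained cascade
#'
#' The confidence of each patch is the signed Euclidean distance of its
#' standardized stage-one score vector to the combiner hyperplane; positive
#' scores mean background ("non-occupied"), negative cellular.
#'
#' @param model a `cascade_model`.
#' @param features a [extract_feature_sets] result with the configuration
#'   the model was trained with.
#' @return a `confidence_map`: numeric matrix shaped like the patch grid.
#' @export
score_patches <- function(model, features) {
  stopifnot(inherits(model, "cascade_model"),
            inherits(features, "patch_feature_sets"))
  s1 <- stage_one_scores(model, features)
  z <- apply_standardizer(s1, model$combiner$std)
  sc <- hyperplane_distance(z, model$combiner$hp)
  grid <- features$grid
  structure(matrix(sc, grid$n_rows, grid$n_cols, byrow = TRUE),
            patch_size = grid$patch_size, image_size = grid$image_size,
            class = c("confidence_map", "matrix", "array"))
}

# Dip-free (unimodal) check on a score histogram: the smoothed counts rise
# to a single peak then fall, plateaus allowed. A light moving average
# keeps sampling noise from reading as extra modes.
histogram_unimodal <- function(x, nbins = 8L) {
  if (length(unique(x)) < 3) return(TRUE)
  h <- fixed_histogram(x, min(x), max(x), nbins)
  h <- as.numeric(stats::filter(c(h[1], h, h[nbins]), rep(1 / 3, 3),
                                sides = 2))[2:(nbins + 1)]
  d <- diff(h)
  s <- sign(d[d != 0])
  all(diff(s) <= 0)  # rises, then falls: sign pattern +...+-...-
}

#' Threshold a confidence map into patch labels
#'
#' `"otsu"` (default) selects the cut maximizing between-class variance of
#' the scores — the automatic threshold of the pipeline — but clamps to 0
#' when the score distribution looks single-class (all one sign and
#' unimodal), where an unsupervised split would be spurious. `"svm-zero"`
#' uses the SVM decision boundary directly.
#'
#' @param confidence a `confidence_map` (or any numeric matrix of scores).
#' @param method `"otsu"` or `"svm-zero"`.
#' @return logical matrix of patch labels (`TRUE` = background), with the
#'   chosen threshold as attribute `threshold`.
#' @export
threshold_confidence <- function(confidence, method = c("otsu", "svm-zero")) {
  method <- match.arg(method)
  sc <- as.vector(confidence)
  thr <- if (method == "svm-zero") 0
  else if ((all(sc >= 0) || all(sc <= 0)) && histogram_unimodal(sc)) 0
  else otsu_threshold(sc)
  out <- matrix(sc > thr, nrow(confidence), ncol(confidence))
  attr(out, "threshold") <- thr
  out
}

#' Save / load a cascade model
#'
#' Models are written as versioned JSON text (weights, biases,
#' standardization parameters, feature configuration, seed) at full double
#' precision, so a load reproduces scores exactly.
#'
#' @param model a `cascade_model`.
#' @param path file path.
#' @return `load_cascade` returns the model; `save_cascade` the path,
#'   invisibly.
#' @export
save_cascade <- function(model, path) {
  jsonlite::write_json(strip_classes(model), path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  raw$meta$config <- do.call(patch_feature_config, raw$meta$config)
  raw$stage_one <- lapply(raw$stage_one, identity)
  structure(raw, class = "cascade_model")
}
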