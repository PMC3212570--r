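test_that("cascade has five stage-one SVMs and a length-5 combiner", {
  model <- wound_model()$cascade
  expect_length(model$stage_one, 5)
  expect_length(model$combiner$hp$w, 5)
  expect_equal(model$meta$patch_size, 20L)
})

test_that("cascade training requires both patch classes", {
  pair <- generate_wound_image(synth_params(wound_shape = "none",
                                            wound_area_fraction = 0, rng_seed = 1))
  expect_error(train_cascade(list(pair)), "single")
})

test_that("confidence is the signed distance to the combiner hyperplane", {
  model <- wound_model()$cascade
  pair <- generate_wound_image(synth_params(rng_seed = 51))
  grid <- build_patch_grid(pair$image, 20)
  feats <- extract_feature_sets(pair$image, grid)
  conf <- score_patches(model, feats)

  # positive scale invariance of the hyperplane
  scaled <- model
  for (cc in 3) {
    scaled$combiner$hp$w <- model$combiner$hp$w * cc
    scaled$combiner$hp$b <- model$combiner$hp$b * cc
  }
  conf2 <- score_patches(scaled, feats)
  expect_equal(unclass(conf), unclass(conf2), tolerance = 1e-12)

  # truth-background patches score above truth-cellular patches
  labels <- matrix(multicellseg:::patch_labels_from_mask(pair$mask, grid),
                   grid$n_rows, grid$n_cols, byrow = TRUE)
  expect_gt(mean(conf[labels]), mean(conf[!labels]))
})

test_that("a hand-built averaging combiner reduces to the stage-one mean", {
  model <- wound_model()$cascade
  pair <- generate_wound_image(synth_params(rng_seed = 52))
  feats <- extract_feature_sets(pair$image, build_patch_grid(pair$image, 20))
  s1 <- multicellseg:::stage_one_scores(model, feats)

  avg <- model
  avg$combiner$hp <- list(w = rep(1 / 5, 5), b = 0)
  avg$combiner$std <- list(center = rep(0, 5), scale = rep(1, 5))
  conf <- score_patches(avg, feats)
  # signed distance of the averaging hyperplane = mean * sqrt(5)
  expect_equal(as.vector(t(unclass(conf))), rowMeans(s1) * sqrt(5),
               tolerance = 1e-12)

  # a feature vector on the hyperplane scores exactly zero
  hp <- list(w = c(1, -2), b = 0.5)
  on_plane <- c(0.5, 0.5)  # 0.5 - 1 + 0.5 = 0
  expect_equal(multicellseg:::hyperplane_distance(matrix(on_plane, 1), hp), 0)
})

test_that("automatic thresholding separates bimodal scores and clamps single-class", {
  sc <- matrix(c(rep(-1, 50), rep(1, 50)), 10, 10)
  lab <- threshold_confidence(sc, "otsu")
  thr <- attr(lab, "threshold")
  expect_gt(thr, -1); expect_lt(thr, 1)
  expect_equal(sum(lab), 50)

  # svm-zero and otsu agree on well-separated bimodal scores
  lab0 <- threshold_confidence(sc, "svm-zero")
  expect_identical(unclass(lab), unclass(lab0))

  # all-negative scores: svm-zero gives no background; otsu clamps to 0
  neg <- matrix(with_seed_test(1, -abs(rnorm(100, -3))), 10, 10)
  expect_equal(sum(threshold_confidence(neg, "svm-zero")), 0)
  expect_equal(sum(threshold_confidence(neg, "otsu")), 0)
})

test_that("score-threshold selection matches a brute-force Otsu oracle", {
  for (seed in 1:5) {
    x <- with_seed_test(seed, c(rnorm(40, -2), rnorm(30, 1.5)))
    expect_equal(multicellseg:::otsu_threshold(x), oracle_otsu(x))
  }
})

test_that("cascade models serialize to JSON and reproduce scores exactly", {
  model <- wound_model()$cascade
  pair <- generate_wound_image(synth_params(rng_seed = 53))
  feats <- extract_feature_sets(pair$image, build_patch_grid(pair$image, 20))
  conf <- score_patches(model, feats)

  path <- withr::local_tempfile(fileext = ".json")
  save_cascade(model, path)
  model2 <- load_cascade(path)
  conf2 <- score_patches(model2, feats)
  expect_identical(unclass(conf), unclass(conf2))
})

test_that("stacking does not lose accuracy relative to the best single feature set", {
  # the rationale for the combiner: its AUC matches or beats every
  # stage-one SVM on held-out data (three independent replicates)
  for (seed in c(201, 301, 401)) {
    train <- lapply(1:3, function(i) generate_wound_image(
      synth_params(image_size = c(120, 120), rng_seed = seed + i)))
    test <- lapply(4:6, function(i) generate_wound_image(
      synth_params(image_size = c(120, 120), rng_seed = seed + i)))
    model <- train_cascade(train, seed = seed)
    scores <- list(); labels <- logical(0)
    s1 <- NULL
    for (pair in test) {
      grid <- build_patch_grid(pair$image, 20)
      feats <- extract_feature_sets(pair$image, grid)
      s1 <- rbind(s1, multicellseg:::stage_one_scores(model, feats))
      conf <- score_patches(model, feats)
      scores[[length(scores) + 1]] <- as.vector(t(unclass(conf)))
      labels <- c(labels, multicellseg:::patch_labels_from_mask(pair$mask, grid))
    }
    combined <- unlist(scores)
    auc_combined <- roc_curve(combined, labels)$auc
    auc_single <- vapply(1:5, function(k) roc_curve(s1[, k], labels)$auc, numeric(1))
    expect_gte(auc_combined, max(auc_single) - 0.01)
  }
})
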