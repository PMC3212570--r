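test_that("background components match a flood-fill oracle", {
  # single isolated patch
  lab <- matrix(FALSE, 5, 5); lab[3, 3] <- TRUE
  comps <- extract_background_components(lab)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$area, 1L)
  expect_equal(comps[[1]]$patches, matrix(c(2L, 2L), 1))

  # all background: one component covering the grid
  all_bg <- matrix(TRUE, 4, 6)
  expect_length(extract_background_components(all_bg), 1)
  expect_equal(extract_background_components(all_bg)[[1]]$area, 24L)

  # checkerboard under 4-connectivity: every background patch isolated
  cb <- outer(1:6, 1:6, function(r, c) (r + c) %% 2 == 0)
  expect_length(extract_background_components(cb, 4L), sum(cb))
  # same checkerboard under 8-connectivity: all diagonal-linked
  expect_length(extract_background_components(cb, 8L), 1)

  # random grids against the independent flood fill
  for (seed in 1:6) {
    rnd <- matrix(with_seed_test(seed, runif(48) < 0.4), 6, 8)
    for (conn in c(4L, 8L)) {
      expect_length(extract_background_components(rnd, conn),
                    oracle_component_count(rnd, conn))
    }
  }

  # deterministic ordering by (min row, min col)
  two <- matrix(FALSE, 4, 4); two[4, 1] <- TRUE; two[1, 4] <- TRUE
  comps2 <- extract_background_components(two)
  expect_equal(comps2[[1]]$patches[1, 1], 0L)  # top component first
})

test_that("region features pool texture over the component", {
  pair <- generate_wound_image(synth_params(rng_seed = 61))
  model <- wound_model()
  grid <- build_patch_grid(pair$image, 20)
  feats <- extract_feature_sets(pair$image, grid)
  conf <- score_patches(model$cascade, feats)
  plab <- threshold_confidence(conf)
  comps <- extract_background_components(plab)
  expect_gt(length(comps), 0)

  fv <- compute_region_features(pair$image, conf, comps[[1]], plab)
  expect_length(fv, 4 + 16 + 4 + 1)
  expect_true(all(is.finite(fv)))
  # pooled gradient histogram (entries 5..20) sums to 1
  expect_equal(sum(fv[5:20]), 1, tolerance = 1e-9)

  # area-1 component: log-area 0, confidence stats equal that patch's score
  one <- structure(list(patches = matrix(c(0L, 0L), 1), area = 1L),
                   class = "region_component")
  fv1 <- compute_region_features(pair$image, conf, one, plab)
  expect_equal(fv1[1], 0)
  expect_equal(fv1[2], conf[1, 1])
  expect_equal(fv1[3], conf[1, 1])

  # a planted component inside cellular texture carries more gradient
  # energy than a same-size component inside the true wound
  cell_patch <- which(!plab, arr.ind = TRUE)[1, ] - 1L
  wound_patch <- which(plab, arr.ind = TRUE)[1, ] - 1L
  area1 <- function(rc) structure(list(patches = matrix(as.integer(rc), 1),
                                       area = 1L), class = "region_component")
  fv_planted <- compute_region_features(pair$image, conf, area1(cell_patch), plab)
  fv_wound <- compute_region_features(pair$image, conf, area1(wound_patch), plab)
  # mean gradient-magnitude bin of the pooled histogram sits higher for the
  # textured (cellular) component
  mean_bin <- function(fv) sum(fv[5:20] * seq_len(16))
  expect_gt(mean_bin(fv_planted), mean_bin(fv_wound))
})

test_that("region filtering vetoes planted false components and is monotone", {
  model <- wound_model()
  pair <- generate_wound_image(synth_params(rng_seed = 62))
  grid <- build_patch_grid(pair$image, 20)
  feats <- extract_feature_sets(pair$image, grid)
  conf <- score_patches(model$cascade, feats)
  plab <- threshold_confidence(conf)

  # no components: labels unchanged
  none <- filter_regions(model$region, list(), plab, pair$image, conf)
  expect_equal(as.vector(none), as.vector(plab))

  # plant a false background patch inside cellular area (not touching any
  # existing background patch), then filter
  planted_lab <- plab
  nb <- rbind(FALSE, plab[-nrow(plab), ]) | rbind(plab[-1, ], FALSE) |
    cbind(FALSE, plab[, -ncol(plab)]) | cbind(plab[, -1], FALSE)
  cell_patch <- which(!plab & !nb, arr.ind = TRUE)[1, ]
  planted_lab[cell_patch[1], cell_patch[2]] <- TRUE
  comps <- extract_background_components(planted_lab)
  out <- filter_regions(model$region, comps, planted_lab, pair$image, conf)
  expect_lte(sum(out), sum(planted_lab))           # monotone
  expect_false(out[cell_patch[1], cell_patch[2]])  # veto of the planted patch
  dec <- attr(out, "decisions")
  expect_equal(nrow(dec), length(comps))

  # the true wound component survives
  expect_gt(sum(out), 0)
})

test_that("region training is deterministic and serializes exactly", {
  train <- wound_training_pairs()[1:2]
  cascade <- wound_model()$cascade
  r1 <- train_region_classifier(train, cascade, seed = 5)
  r2 <- train_region_classifier(train, cascade, seed = 5)
  expect_identical(r1$hp, r2$hp)

  path <- withr::local_tempfile(fileext = ".json")
  save_region_model(r1, path)
  r3 <- load_region_model(path)
  expect_equal(r3$hp$w, r1$hp$w, tolerance = 0)
  expect_equal(r3$std$center, r1$std$center, tolerance = 0)
})
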