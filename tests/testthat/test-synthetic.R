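test_that("wound generator honors area fraction, degenerate cases and determinism", {
  # degenerate: no wound
  p0 <- generate_wound_image(synth_params(wound_shape = "none",
                                          wound_area_fraction = 0, rng_seed = 1))
  expect_false(any(p0$mask))
  expect_identical(dim(p0$image$intensities), dim(p0$mask))

  # band wound: background fraction within +/- 5% absolute of the target
  for (frac in c(0.2, 0.5)) {
    p <- generate_wound_image(synth_params(wound_area_fraction = frac, rng_seed = 7))
    expect_lt(abs(mean(p$mask) - frac), 0.05)
  }

  # determinism and seed sensitivity
  a <- generate_wound_image(synth_params(rng_seed = 11))
  b <- generate_wound_image(synth_params(rng_seed = 11))
  c <- generate_wound_image(synth_params(rng_seed = 12))
  expect_identical(a$image$intensities, b$image$intensities)
  expect_identical(unclass(a$mask), unclass(b$mask))
  expect_false(identical(a$image$intensities, c$image$intensities))

  # parameter validation
  expect_error(synth_params(wound_area_fraction = 1.2), "fraction")
  expect_error(synth_params(image_size = c(32, 200)), "64")
})

test_that("wound boundary is irregular, not a straight line", {
  p <- generate_wound_image(synth_params(rng_seed = 5))
  # left boundary column index per row varies by several pixels
  left_edge <- apply(unclass(p$mask), 1, function(r) which(r)[1])
  expect_gt(diff(range(left_edge)), 4)
})

test_that("wound series closes linearly and per-frame texture varies", {
  base <- synth_params(rng_seed = 3, wound_area_fraction = 0.4)

  # zero closure: equal truth areas (up to boundary perturbation)
  s0 <- generate_wound_series(base, 3, 0)
  areas0 <- vapply(s0, function(p) mean(p$mask), numeric(1))
  expect_true(all(abs(areas0 - 0.4) < 0.05))
  expect_false(identical(s0[[1]]$image$intensities, s0[[2]]$image$intensities))

  # closure 0.25 over 5 frames: areas proportional to 1, .75, .5, .25, 0
  s <- generate_wound_series(base, 5, 0.25)
  fr <- vapply(s, function(p) mean(p$mask), numeric(1))
  expect_true(all(abs(fr - 0.4 * c(1, .75, .5, .25, 0)) < 0.05 * 0.4 + 0.01))

  # linearity of truth areas: |Pearson r| > 0.99 for rate 0.2, 6 frames
  s6 <- generate_wound_series(synth_params(rng_seed = 9, wound_area_fraction = 0.3),
                              6, 0.2)
  a6 <- vapply(s6, function(p) sum(p$mask), numeric(1))
  expect_gt(abs(cor(a6, 0:5)), 0.99)

  expect_error(generate_wound_series(base, 1, 0.1), "n_frames")
  expect_error(generate_wound_series(base, 4, -0.1), "closure_rate")
})

test_that("scatter generator separates the classes by construction", {
  ns <- lapply(1:6, function(i) generate_scatter_image(FALSE, scatter_params(i)))
  sc <- lapply(1:6, function(i) generate_scatter_image(TRUE, scatter_params(100 + i)))

  n_comp <- function(p) oracle_component_count(!unclass(p$mask), 8L)
  expect_gt(min(vapply(sc, n_comp, numeric(1))),
            max(vapply(ns, n_comp, numeric(1))))

  # both classes hit the configured cellular area within +/- 10%
  area <- function(p) mean(!p$mask)
  expect_true(all(abs(vapply(ns, area, numeric(1)) - 0.35) < 0.035))
  expect_true(all(abs(vapply(sc, area, numeric(1)) - 0.35) < 0.035))

  # the texture statistics differ: mean LBP histograms well separated in L1
  d_ns <- colMeans(t(vapply(ns, function(p)
    as.numeric(scatter_descriptor(p$image, p$mask)), numeric(10))))
  d_sc <- colMeans(t(vapply(sc, function(p)
    as.numeric(scatter_descriptor(p$image, p$mask)), numeric(10))))
  expect_gt(sum(abs(d_ns - d_sc)), 0.1)
})

test_that("texture strength monotonically increases cellular gradient contrast", {
  diffs <- vapply(c(0.05, 0.12, 0.25), function(strength) {
    p <- generate_wound_image(synth_params(cell_texture_strength = strength,
                                           rng_seed = 21))
    g <- multicellseg:::image_gradient(p$image$intensities)$mag
    mean(g[!p$mask]) - mean(g[p$mask])
  }, numeric(1))
  expect_true(all(diff(diffs) > 0))
})

test_that("fixture sets round-trip through image files and a manifest", {
  dir <- withr::local_tempdir()
  pairs <- lapply(1:2, function(i) generate_wound_image(synth_params(
    image_size = c(64, 64), rng_seed = i)))
  mf <- write_fixture_set(pairs, dir, "t", format = "png")
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  img <- read_calibrated_image(file.path(dir, mf$filename[1]), mf$pixel_size_um[1])
  msk <- read_mask(file.path(dir, mf$mask[1]))
  expect_identical(dim(img$intensities), dim(pairs[[1]]$image$intensities))
  expect_identical(unclass(msk), unclass(pairs[[1]]$mask))
  # 8-bit quantization + read-time min-max normalization preserve structure
  expect_gt(cor(as.vector(img$intensities),
                as.vector(pairs[[1]]$image$intensities)), 0.999)
})
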