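mask_of <- function(m) segmentation_mask(m, stage = "truth")

test_that("pixel accuracy counts matching pixels", {
  truth <- mask_of(matrix(c(TRUE, TRUE, FALSE, FALSE), 2, byrow = TRUE))
  expect_equal(pixel_accuracy(truth, truth), 1.0)
  comp <- mask_of(!matrix(c(TRUE, TRUE, FALSE, FALSE), 2, byrow = TRUE))
  expect_equal(pixel_accuracy(comp, truth), 0.0)
  pred <- mask_of(matrix(c(TRUE, FALSE, FALSE, FALSE), 2, byrow = TRUE))
  expect_equal(pixel_accuracy(pred, truth), 0.75)
  expect_error(pixel_accuracy(mask_of(matrix(TRUE, 2, 3)), truth), "shape")
})

test_that("ROC curves follow their defining examples", {
  # perfect separation
  r1 <- roc_curve(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(r1$auc, 1.0)

  # constant confidence: diagonal, two informative points, AUC 1/2
  r2 <- roc_curve(rep(0.3, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(r2$auc, 0.5)
  expect_equal(r2$fpr, c(0, 1))
  expect_equal(r2$tpr, c(0, 1))

  # 4 pixels: 3 concordant pairs of 4 -> AUC 0.75
  r3 <- roc_curve(c(0.9, 0.8, 0.4, 0.1), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(r3$auc, 0.75)

  expect_error(roc_curve(c(1, 2), c(TRUE, TRUE)), "both classes")
})

test_that("ROC curves are monotone from (0,0) to (1,1) and AUC equals U/(n+ n-)", {
  for (seed in 1:10) {
    sc <- with_seed_test(seed, round(rnorm(60), 1))  # ties included
    tr <- with_seed_test(seed + 99, runif(60) < 0.4)
    if (length(unique(tr)) < 2) next
    r <- roc_curve(sc, tr)
    expect_equal(r$fpr[1], 0); expect_equal(r$tpr[1], 0)
    expect_equal(r$fpr[length(r$fpr)], 1); expect_equal(r$tpr[length(r$tpr)], 1)
    expect_true(all(diff(r$fpr) >= 0) && all(diff(r$tpr) >= 0))
    # Mann-Whitney U with midranks (the oracle identity)
    u <- sum(rank(sc)[tr]) - sum(tr) * (sum(tr) + 1) / 2
    expect_equal(r$auc, u / (sum(tr) * sum(!tr)), tolerance = 1e-12)
  }
})

test_that("ROC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  sc <- with_seed_test(7, rnorm(80))
  tr <- with_seed_test(8, runif(80) < 0.5)
  r <- roc_curve(sc, tr)
  pr <- pROC::roc(response = tr, predictor = sc, quiet = TRUE,
                  direction = "<", levels = c(FALSE, TRUE))
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
})

test_that("vertical ROC averaging behaves on the defining cases", {
  r <- roc_curve(c(0.9, 0.8, 0.4, 0.1), c(TRUE, FALSE, TRUE, FALSE))
  avg1 <- average_rocs(list(r))
  expect_equal(avg1$auc, r$auc, tolerance = 0.01)
  avg2 <- average_rocs(list(r, r))
  expect_equal(avg2$tpr, avg1$tpr)

  perfect <- roc_curve(c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE))
  diag <- roc_curve(rep(0, 4), c(TRUE, FALSE, TRUE, FALSE))
  mixed <- average_rocs(list(perfect, diag))
  expect_equal(mixed$auc, 0.75, tolerance = 0.01)
})

test_that("TPR-matched threshold accuracy enumerates operating points", {
  sc <- c(0.9, 0.8, 0.4, 0.1); tr <- c(TRUE, FALSE, TRUE, FALSE)
  # reference 0: empty prediction; accuracy = cellular fraction
  expect_equal(as.numeric(matched_threshold_accuracy(0, sc, tr)), 0.5)
  # reference 0.5: first threshold with TPR >= 0.5 tags only the top pixel
  expect_equal(as.numeric(matched_threshold_accuracy(0.5, sc, tr)), 0.75)
  # perfect separation at TPR 1
  expect_equal(as.numeric(matched_threshold_accuracy(
    1, c(1, 1, 0, 0), c(TRUE, TRUE, FALSE, FALSE))), 1.0)
  expect_error(matched_threshold_accuracy(1.5, sc, tr), "reference_tpr")
})

test_that("paired t-test matches stats::t.test and flags degenerate input", {
  a <- c(0.95, 0.93, 0.97, 0.91); b <- c(0.92, 0.90, 0.96, 0.88)
  res <- paired_accuracy_test(a, b)
  expect_false(res$degenerate)
  expect_equal(res$p_value, t.test(a, b, paired = TRUE)$p.value)

  same <- paired_accuracy_test(a, a)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1.0)
  expect_error(paired_accuracy_test(a, b[1:3]), "equal-length")
})

test_that("rank sum test enumerates exactly for small samples", {
  # x = {1,2}, y = {3,4}: one-sided tail 1/6, two-sided 1/3
  res <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(res$p_value, 1 / 3)
  expect_match(res$method, "exact")

  # symmetry of the two-sided p
  expect_equal(rank_sum_test(c(3, 4), c(1, 2))$p_value, 1 / 3)

  # identical samples: p = 1
  expect_equal(rank_sum_test(c(2, 2, 2), c(2, 2, 2))$p_value, 1)

  # exact branch agrees with stats::wilcox.test on untied data
  x <- c(1.2, 3.4, 2.2, 5.1); y <- c(2.8, 6.3, 4.4)
  expect_equal(rank_sum_test(x, y)$p_value,
               wilcox.test(x, y, exact = TRUE)$p.value)

  # large-sample branch agrees with the uncorrected normal approximation
  xl <- with_seed_test(1, rnorm(10)); yl <- with_seed_test(2, rnorm(9, 0.8))
  expect_equal(rank_sum_test(xl, yl)$p_value,
               wilcox.test(xl, yl, exact = FALSE, correct = FALSE)$p.value,
               tolerance = 1e-12)
  expect_error(rank_sum_test(numeric(0), c(1)), "nonempty")
})
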