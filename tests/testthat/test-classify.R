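test_that("metric engine matches the direct formulas exhaustively", {
  direct <- function(tp, fp, tn, fn) {
    den <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
    list(sen = tp / (tp + fn), spe = tn / (tn + fp),
         acc = (tp + tn) / (tp + fp + tn + fn),
         mcc = if (den == 0) 0 else (tp * tn - fp * fn) / sqrt(den))
  }
  set.seed(18)
  quads <- cbind(sample(0:20, 60, TRUE), sample(0:20, 60, TRUE),
                 sample(0:20, 60, TRUE), sample(0:20, 60, TRUE))
  quads <- quads[rowSums(quads) > 0, ]
  for (i in seq_len(nrow(quads))) {
    q <- quads[i, ]
    m <- suppressWarnings(compute_metrics(confusion_counts(q[1], q[2], q[3],
                                                           q[4])))
    w <- direct(q[1], q[2], q[3], q[4])
    expect_equal(m$acc, w$acc)
    expect_equal(m$mcc, w$mcc)
    if (q[1] + q[4] > 0) expect_equal(m$sen, w$sen)
    if (q[3] + q[2] > 0) expect_equal(m$spe, w$spe)
  }
  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "zero")
})

test_that("perfect and class-swapped classifiers behave symmetrically", {
  perfect <- compute_metrics(confusion_counts(14, 0, 19, 0))
  expect_equal(c(perfect$sen, perfect$spe, perfect$acc, perfect$mcc),
               c(1, 1, 1, 1))
  a <- compute_metrics(confusion_counts(9, 4, 11, 5))
  b <- compute_metrics(confusion_counts(11, 5, 9, 4))  # swap classes
  expect_equal(a$sen, b$spe)
  expect_equal(a$spe, b$sen)
  expect_equal(a$acc, b$acc)
  expect_equal(a$mcc, b$mcc)
})

test_that("MCC zero-denominator convention is 0 with a flag", {
  expect_warning(m <- compute_metrics(confusion_counts(0, 0, 5, 5)),
                 "MCC")
  expect_equal(m$mcc, 0)
  expect_true(m$mcc_flagged)
})

test_that("the eight feature combinations are fixed and all contain {1,2}", {
  combos <- enumerate_combos()
  expect_length(combos, 8)
  expect_equal(combos[[1]], c(1L, 2L))
  expect_equal(combos[[8]], 1:5)
  expect_true(all(vapply(combos, function(x) all(c(1L, 2L) %in% x),
                         logical(1))))
  expect_false(any(duplicated(lapply(combos, paste, collapse = ","))))
})

test_that("LOO SVM is perfect on separable clusters and deterministic", {
  set.seed(19)
  n <- 10
  feats <- rbind(matrix(rnorm(2 * n, mean = 0, sd = 0.05), ncol = 2),
                 matrix(rnorm(2 * n, mean = 1, sd = 0.05), ncol = 2))
  labels <- rep(c("NPDR", "PDR"), each = n)
  cfg <- svm_config(c_grid = 2^seq(-4, 4, 2), g_grid = 2^seq(-4, 4, 2))
  r1 <- loo_evaluate(feats, labels, c(1L, 2L), cfg)
  expect_equal(r1$metrics$acc, 1)
  expect_equal(r1$metrics$mcc, 1)
  r2 <- loo_evaluate(feats, labels, c(1L, 2L), cfg)
  expect_identical(r1$predictions, r2$predictions)
})

test_that("identical features for all eyes predict one class only", {
  feats <- matrix(0.5, 12, 2)
  labels <- rep(c("NPDR", "PDR"), each = 6)
  r <- suppressWarnings(loo_evaluate(feats, labels, c(1L, 2L),
                                     svm_config(c_grid = 1, g_grid = 1)))
  expect_true(r$metrics$sen == 0 || r$metrics$spe == 0)
})

test_that("label permutation drives LOO accuracy to chance", {
  set.seed(20)
  n <- 40
  feats <- matrix(rnorm(2 * n), ncol = 2)
  cfg <- svm_config(c_grid = 10, g_grid = 2)  # fixed flexible (c, g): no grid search, no LOO majority bias
  accs <- replicate(60, {
    labels <- sample(rep(c("NPDR", "PDR"), each = n / 2))
    suppressWarnings(loo_evaluate(feats, labels, c(1L, 2L), cfg))$metrics$acc
  })
  expect_lt(abs(mean(accs) - 0.5), 0.05)
})

test_that("severity report covers 8 combos x groups with valid percentages", {
  set.seed(21)
  mk <- function() {
    lab <- rep(c("NPDR", "PDR"), c(6, 8))
    data.frame(eye_id = sprintf("e%02d", 1:14), label = lab,
               avg_area_mm2 = runif(14, 0, 0.3) + 0.2 * (lab == "PDR"),
               amount = rpois(14, 5) + 4 * (lab == "PDR"),
               avg_distance_um = runif(14, 200, 1500),
               avg_altitude_um = runif(14, 20, 80),
               avg_reflectivity = runif(14, 60, 100))
  }
  tabs <- list(he = mk(), hrf_excl = mk(), hrf_incl = mk())
  rep_df <- severity_report(tabs, svm_config(c_grid = 2^c(-2, 0, 2),
                                             g_grid = 2^c(-2, 0, 2)))
  expect_equal(nrow(rep_df), 24)
  expect_equal(unique(rep_df$group), c("he", "hrf_excl", "hrf_incl"))
  expect_equal(rep_df$combo[1:8],
               vapply(enumerate_combos(), paste, "", collapse = ","))
  expect_true(all(rep_df$sen >= 0 & rep_df$sen <= 100))
  expect_true(all(rep_df$acc >= 0 & rep_df$acc <= 100))
  expect_true(all(rep_df$mcc >= -100 & rep_df$mcc <= 100))
  txt <- format_severity_report(rep_df)
  expect_length(strsplit(txt, "\n")[[1]], 24)
})

test_that("single-class folds and bad labels are rejected", {
  feats <- matrix(rnorm(8), 4, 2)
  expect_error(loo_evaluate(feats, c("NPDR", "NPDR", "NPDR", "PDR"),
                            c(1L, 2L)), "2 eyes per class")
  expect_error(loo_evaluate(feats, c("x", "y", "x", "y"), c(1L, 2L)),
               "NPDR")
})
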