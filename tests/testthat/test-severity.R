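test_that("volume measurement converts voxel counts to cc exactly", {
  m <- array(FALSE, c(10, 10, 10))
  m[seq_len(1000)] <- TRUE
  expect_equal(measure_volume(m, c(1, 1, 1)), 1.0)
  expect_equal(measure_volume(array(FALSE, c(4, 4, 4)), c(1, 1, 1)), 0)
  m2 <- array(FALSE, c(20, 20, 5))
  m2[seq_len(2000)] <- TRUE
  expect_equal(measure_volume(m2, c(0.5, 0.5, 5)), 2.5)
})

test_that("volume is additive over disjoint masks", {
  set.seed(4)
  d <- c(8, 8, 4)
  a <- array(runif(prod(d)) < 0.3, d)
  b <- array(runif(prod(d)) < 0.3, d) & !a
  sp <- c(0.7, 0.7, 3)
  expect_equal(measure_volume(a | b, sp),
               measure_volume(a, sp) + measure_volume(b, sp))
})

test_that("severity dichotomy is >= 25 cc for moderate/severe", {
  expect_equal(as.character(classify_severity(24.9)), "non-hematoma/mild")
  expect_equal(as.character(classify_severity(25.0)), "moderate/severe")
  expect_equal(as.character(classify_severity(0)), "non-hematoma/mild")
  expect_equal(as.character(classify_severity(30, threshold_cc = 50)),
               "non-hematoma/mild")
})

test_that("overlap metrics match direct set counts", {
  d <- c(6, 6, 3)
  U <- array(TRUE, d)
  S <- array(FALSE, d); GT <- array(FALSE, d)
  S[1:4] <- TRUE; GT[3:6] <- TRUE       # |S|=4, |GT|=4, |S∩GT|=2
  m <- overlap_metrics(S, GT, U)
  expect_equal(m$dice, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$precision, 0.5)

  m_id <- overlap_metrics(GT, GT, U)
  expect_equal(m_id$dice, 1); expect_equal(m_id$recall, 1)
  expect_equal(m_id$precision, 1); expect_equal(m_id$specificity, 1)

  S2 <- array(FALSE, d); S2[10:12] <- TRUE
  GT2 <- array(FALSE, d); GT2[20:22] <- TRUE
  expect_equal(overlap_metrics(S2, GT2, U)$dice, 0)

  # empty ground truth: dice/recall undefined, specificity defined
  none <- array(FALSE, d)
  m0 <- overlap_metrics(S2, none, U)
  expect_true(is.na(m0$dice) && is.na(m0$recall))
  expect_false(is.na(m0$specificity))
  m00 <- overlap_metrics(none, none, U)
  expect_true(is.na(m00$precision))
  expect_equal(m00$specificity, 1)

  expect_error(overlap_metrics(S, GT[, , 1:2, drop = FALSE], U), "geometry")
})

test_that("specificity complements are taken within the universe", {
  d <- c(6, 6, 1)
  U <- array(FALSE, d); U[1:18] <- TRUE
  S <- array(FALSE, d); S[1:6] <- TRUE
  GT <- array(FALSE, d); GT[1:3] <- TRUE
  m <- overlap_metrics(S, GT, U)
  # negatives within U: 15; false positives: 3 -> specificity 12/15
  expect_equal(m$specificity, 12 / 15)
})

test_that("severity confusion reproduces its closed-form statistics", {
  # symmetric counts: everything 50%
  sym <- severity_confusion(counts = matrix(c(1, 1, 1, 1), 2, 2))
  expect_equal(sym$stats$recall_pct, 50)
  expect_equal(sym$stats$specificity_pct, 50)

  # perfect agreement
  perf <- severity_confusion(reference_cc = c(10, 10, 40, 60),
                             computed_cc = c(5, 12, 30, 70))
  expect_equal(perf$stats$recall_pct, 100)
  expect_equal(perf$stats$specificity_pct, 100)
  expect_equal(perf$stats$f1_pct, 100)

  # transposing the matrix swaps the roles of the two lists: recall of
  # the transpose equals precision-like reading of the original
  cm <- matrix(c(24, 1, 2, 83), 2, 2)
  a <- severity_confusion(counts = cm)
  b <- severity_confusion(counts = t(cm))
  expect_equal(a$stats$recall_pct,
               round(100 * cm[2, 2] / (cm[2, 2] + cm[2, 1]), 2))
  expect_equal(b$stats$recall_pct,
               round(100 * cm[2, 2] / (cm[2, 2] + cm[1, 2]), 2))

  expect_error(severity_confusion(reference_cc = 1:3, computed_cc = 1:2),
               "length")
})

test_that("volume agreement recovers exact regression and Bland-Altman forms", {
  ref <- c(10, 50, 100, 200)

  ident <- volume_agreement(ref, ref)
  expect_equal(ident$slope, 1)
  expect_equal(ident$bias_cc, 0)
  expect_equal(ident$loa_low_cc, 0)
  expect_equal(ident$loa_high_cc, 0)

  shift <- volume_agreement(ref, ref + 5)
  expect_equal(shift$slope, 1)
  expect_equal(shift$bias_cc, 5)

  scaled <- volume_agreement(ref, 0.9 * ref)
  expect_equal(scaled$slope, 0.9)
  expect_equal(scaled$bias_cc, -0.1 * mean(ref))
  expect_equal(scaled$slope_origin, 0.9)

  expect_error(volume_agreement(c(5, 5, 5), c(1, 2, 3)), "zero variance")
  expect_error(volume_agreement(c(1, 2), c(1, 2)), "at least 3")
})

test_that("autoplot produces the regression and Bland-Altman panels", {
  va <- volume_agreement(c(10, 50, 100, 200), c(12, 48, 90, 210))
  plots <- ggplot2::autoplot(va)
  expect_s3_class(plots$regression, "ggplot")
  expect_s3_class(plots$bland_altman, "ggplot")
})

test_that("inter-rater comparison stratifies mean Dice by reference volume", {
  d <- c(20, 20, 10)
  sp <- c(2, 2, 5)       # voxel = 0.02 cc
  blob <- function(n) { m <- array(FALSE, d); m[seq_len(n)] <- TRUE; m }

  # identical pair (small), disjoint pair (small), constructed overlap
  # (large: 2000 voxels x 0.02 cc = 40 cc reference)
  a <- list(c1 = blob(100), c2 = blob(100), c3 = blob(2000))
  b <- list(c1 = blob(100),
            c2 = { m <- array(FALSE, d); m[101:200] <- TRUE; m },
            c3 = blob(1600))
  cmp <- interrater_compare(a, b, sp, strata_cc = 25)
  expect_equal(cmp$per_case$dice[cmp$per_case$case == "c1"], 1)
  expect_equal(cmp$per_case$dice[cmp$per_case$case == "c2"], 0)
  expect_equal(cmp$per_case$dice[cmp$per_case$case == "c3"],
               2 * 1600 / (1600 + 2000))
  small <- cmp$per_stratum[cmp$per_stratum$stratum == "<25 cc", ]
  expect_equal(small$mean_dice, 0.5)
  expect_equal(small$n, 2L)

  names(b)[2] <- "zz"
  expect_error(interrater_compare(a, b, sp), "case ids")
})

test_that("severity_report combines volume and class", {
  m <- array(FALSE, c(30, 30, 30))
  m[seq_len(26000)] <- TRUE
  rep <- severity_report(m, c(1, 1, 1))
  expect_equal(rep$volume_cc, 26)
  expect_equal(as.character(rep$severity), "moderate/severe")
})
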