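test_that("confusion counts cross-tabulate predictions against outcome", {
  pred <- rep(c(TRUE, FALSE), c(6, 4))
  truth <- pred
  cc <- confusion_counts(pred, truth)
  expect_equal(unlist(cc[c("tp", "fp", "fn", "tn")]), c(tp = 6, fp = 0, fn = 0, tn = 4))

  # group-level margins of the published cohort: 61/35 tap split among 96
  # responders, 28/42 among 70 non-responders
  pred <- rep(c(TRUE, FALSE, TRUE, FALSE), c(61, 35, 28, 42))
  truth <- rep(c(TRUE, FALSE), c(96, 70))
  cc <- confusion_counts(pred, truth)
  expect_equal(unlist(cc[c("tp", "fp", "fn", "tn")]), c(tp = 61, fp = 28, fn = 35, tn = 42))

  cc <- confusion_counts(rep(FALSE, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(cc$tp + cc$fp, 0)
  expect_error(confusion_counts(TRUE, c(TRUE, FALSE)), "length")
  expect_equal(confusion_counts(c(TRUE, NA), c(TRUE, TRUE))$n_excluded, 1L)
})

test_that("diagnostic performance reproduces the published 2-dp single-marker rows", {
  tap <- diagnostic_performance(as_confusion_counts(61, 28, 35, 42))
  expect_equal(tap$sensitivity_2dp, 0.64)
  expect_equal(tap$specificity_2dp, 0.60)
  expect_equal(tap$auc_2dp, 0.62)

  desh <- diagnostic_performance(as_confusion_counts(53, 8, 43, 62))
  expect_equal(desh$sensitivity_2dp, 0.55)
  expect_equal(desh$specificity_2dp, 0.89)
  expect_equal(desh$auc_2dp, 0.72)

  perfect <- diagnostic_performance(as_confusion_counts(5, 0, 0, 5))
  expect_equal(unlist(perfect[c("sensitivity", "specificity", "ppv", "npv", "auc")]),
               c(sensitivity = 1, specificity = 1, ppv = 1, npv = 1, auc = 1))
  expect_error(diagnostic_performance(as_confusion_counts(0, 3, 0, 3)), "responder")
})

test_that("performance ratios match hand-computed values on all small 2x2 tables", {
  for (tp in 0:5) for (fp in 0:5) for (fn in 0:5) for (tn in 0:5) {
    if (tp + fn == 0 || tn + fp == 0) next
    perf <- diagnostic_performance(as_confusion_counts(tp, fp, fn, tn))
    expect_identical(perf$sensitivity, tp / (tp + fn))
    expect_identical(perf$specificity, tn / (tn + fp))
    expect_identical(perf$ppv, if (tp + fp == 0) NA_real_ else tp / (tp + fp))
    expect_identical(perf$npv, if (tn + fn == 0) NA_real_ else tn / (tn + fn))
    expect_identical(perf$auc, (perf$sensitivity + perf$specificity) / 2)
  }
})

test_that("binary AUC is the three-point trapezoid, symmetric in its arguments", {
  expect_equal(binary_auc(1, 1), 1)
  expect_equal(round_half_away(binary_auc(61 / 96, 42 / 70)), 0.62)
  expect_equal(round_half_away(binary_auc(0.77, 0.67)), 0.72)
  set.seed(17)
  s <- runif(20); p <- runif(20)
  expect_equal(binary_auc(s, p), binary_auc(p, s))
  expect_error(binary_auc(1.2, 0.5), "\\[0, 1\\]")

  # identity with the trapezoid of the dichotomized marker's own ROC
  marker <- c(rep(1, 7), rep(0, 13))
  truth <- c(rep(TRUE, 5), rep(FALSE, 2), rep(TRUE, 3), rep(FALSE, 10))
  perf <- diagnostic_performance(confusion_counts(marker == 1, truth))
  roc <- roc_youden(marker, truth, "higher_is_positive")
  expect_equal(roc$auc, binary_auc(perf$sensitivity, perf$specificity))
})

test_that("ROC handles perfect separation, constant markers, and ties deterministically", {
  r <- roc_youden(c(50, 55, 60, 80, 85, 90), rep(c(TRUE, FALSE), each = 3),
                  "lower_is_positive")
  expect_equal(r$auc, 1)
  expect_equal(r$youden_j_max, 1)
  expect_gt(r$optimal_cutoff, 60)
  expect_lt(r$optimal_cutoff, 80)

  r <- roc_youden(rep(c(1, 2, 3), 2), rep(c(TRUE, FALSE), each = 3), "lower_is_positive")
  expect_equal(r$auc, 0.5)

  r <- roc_youden(rep(7, 8), rep(c(TRUE, FALSE), 4), "lower_is_positive")
  expect_equal(r$auc, 0.5)
  expect_true(r$cutoff_undefined)

  # several thresholds tie on J: the higher-specificity one is returned
  m <- c(1, 2, 3, 10, 11, 12)
  tr <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  r <- roc_youden(m, tr, "lower_is_positive")
  tied <- r$points[abs(r$points$youden_j - r$youden_j_max) < 1e-12, ]
  expect_equal(r$optimal_cutoff, tied$threshold[which.max(tied$specificity)])
})

test_that("trapezoidal AUC equals the normalized Mann-Whitney U with tie credit", {
  set.seed(2024)
  for (i in 1:20) {
    n1 <- sample(5:40, 1); n2 <- sample(5:40, 1)
    x <- c(rnorm(n1, mean = runif(1, 0, 2)), rnorm(n2))
    if (i %% 2 == 0) x <- round(x)  # force ties
    truth <- rep(c(TRUE, FALSE), c(n1, n2))
    r <- roc_youden(x, truth, "higher_is_positive")
    u <- suppressWarnings(stats::wilcox.test(x[truth], x[!truth])$statistic)
    expect_equal(r$auc, unname(u) / (n1 * n2))
  }
})

test_that("ROC AUC and Youden cutoff agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  ca <- c(rnorm(60, 71, 14), rnorm(50, 76, 15))
  truth <- rep(c(TRUE, FALSE), c(60, 50))
  r <- roc_youden(ca, truth, "lower_is_positive")
  ref <- pROC::roc(response = truth, predictor = ca, direction = ">",
                   levels = c(FALSE, TRUE), quiet = TRUE)
  expect_equal(r$auc, as.numeric(pROC::auc(ref)))
  best <- pROC::coords(ref, x = "best", best.method = "youden", transpose = FALSE)
  expect_equal(r$youden_j_max, max(best$sensitivity + best$specificity - 1))
})
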