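test_that("continuous comparison dispatches t-test vs Mann-Whitney via the gates", {
  set.seed(8)
  a <- rnorm(60); b <- rnorm(60)
  r <- compare_continuous(a, b, variable = "x")
  expect_equal(r$test_used, "t_test")
  expect_equal(r$p_value, stats::t.test(a, b, var.equal = TRUE)$p.value)

  skewed <- rlnorm(50, 0, 1)
  r <- compare_continuous(skewed, rnorm(50, 2), variable = "x")
  expect_equal(r$test_used, "mann_whitney")
  expect_lt(stats::shapiro.test(skewed)$p.value, 0.05)  # SW gate really rejects

  # heterogeneous variances break the F gate even under normality
  set.seed(9)
  r <- compare_continuous(rnorm(100, 0, 1), rnorm(100, 0, 6))
  expect_equal(r$test_used, "mann_whitney")

  expect_error(compare_continuous(c(1, 2), rnorm(5)), "at least 3")
})

test_that("identical groups give p = 1 for the tie-corrected Mann-Whitney", {
  x <- rep(c(1, 2, 3, 4), 5)
  r <- compare_continuous(x, x)
  expect_equal(r$test_used, "mann_whitney")  # ties break the SW gate
  expect_equal(r$p_value, 1.0)
})

test_that("chi-square on the tap contingency table matches the closed form and p < 0.01", {
  r <- chi_square_test(c(61, 28, 35, 42), variable = "tap")
  # closed form n(ad-bc)^2 / (row and column products)
  n <- 166
  expected <- n * (61 * 42 - 28 * 35)^2 / (89 * 77 * 96 * 70)
  expect_equal(r$statistic, expected)
  expect_equal(r$statistic, 9.02, tolerance = 0.01)
  expect_equal(r$p_value, 0.0027, tolerance = 0.05)
  expect_lt(r$p_value, 0.01)

  r0 <- chi_square_test(matrix(50, 2, 2))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)
  expect_error(chi_square_test(c(0, 0, 5, 5)), "margins")
})

test_that("forward-LR selection recovers a known coefficient and skips a null one", {
  set.seed(5000)
  n <- 5000
  x1 <- rnorm(n); x2 <- rnorm(n)
  d <- data.frame(y = rbinom(n, 1, stats::plogis(x1)), x1 = x1, x2 = x2)
  fit <- fit_logistic_forward_lr(d, "y", c("x1", "x2"))
  expect_identical(fit$selected, "x1")
  expect_equal(fit$coefficients$estimate, 1.0, tolerance = 0.1)
  expect_equal(fit$coefficients$odds_ratio, exp(fit$coefficients$estimate))
  expect_equal(fit$coefficients$odds_ratio_reversed, 1 / fit$coefficients$odds_ratio)
  expect_true(all(fit$trace$term %in% c("x1", "x2")))
  expect_true("x1" %in% fit$trace$term[fit$trace$action == "add"])
})

test_that("a perfectly predictive covariate raises a separation error", {
  d <- data.frame(y = rep(0:1, each = 30), z = rep(0:1, each = 30) + 0.0)
  expect_error(fit_logistic_forward_lr(d, "y", "z"), "separation")
})

test_that("LR selection is invariant to affine covariate rescaling; CIs transform", {
  set.seed(77)
  n <- 800
  x <- rnorm(n, 70, 15)
  d <- data.frame(y = rbinom(n, 1, stats::plogis(2 - 0.03 * x)), x = x)
  f1 <- fit_logistic_forward_lr(d, "y", "x")
  d2 <- d; d2$x <- (d$x - 70) / 15
  f2 <- fit_logistic_forward_lr(d2, "y", "x")
  expect_equal(f1$trace$lr_statistic, f2$trace$lr_statistic)
  expect_equal(f1$coefficients$estimate * 15, f2$coefficients$estimate)
  expect_equal(f1$coefficients$wald_chi_square, f2$coefficients$wald_chi_square,
               tolerance = 1e-6)
  # SE scales with the covariate, and CI endpoints are exp(est +/- 1.96 se)
  expect_equal(f2$coefficients$std_error, f1$coefficients$std_error * 15)
  expect_equal(f1$coefficients$or_ci_low,
               exp(f1$coefficients$estimate - 1.96 * f1$coefficients$std_error))
  expect_equal(f1$coefficients$or_ci_high,
               exp(f1$coefficients$estimate + 1.96 * f1$coefficients$std_error))
})
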