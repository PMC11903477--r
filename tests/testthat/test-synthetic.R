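test_that("simulated cohorts honor group sizes, determinism, and rule back-filling", {
  c1 <- simulate_cohort(simulation_config(), seed = 42)
  expect_equal(sum(c1$outcome == "responder"), 96)
  expect_equal(sum(c1$outcome == "non_responder"), 70)
  expect_identical(c1, simulate_cohort(simulation_config(), seed = 42))
  expect_false(identical(c1, simulate_cohort(simulation_config(), seed = 43)))
  expect_equal(nrow(validate_cohort(c1)), 0)

  # severity back-fill: Krauss labeling reproduces group membership
  lab <- krauss_responder(c1)
  expect_identical(lab$responder, c1$outcome == "responder")
})

test_that("copula binary rates converge to configured rates at large n", {
  cfg <- simulation_config(n_responders = 100000, n_non_responders = 10)
  big <- simulate_cohort(cfg, seed = 101)
  resp <- big[big$outcome == "responder", ]
  for (v in c("desh", "sym_gait", "com_endocrine")) {
    rate <- cfg$binary$rate_resp[cfg$binary$var == v]
    se <- sqrt(rate * (1 - rate) / nrow(resp))
    expect_lt(abs(mean(resp[[v]]) - rate), 3 * se)
  }
  # tap back-fill preserves the thresholded tap status
  tap <- classify_tap_response(resp)
  rate <- cfg$binary$rate_resp[cfg$binary$var == "tap_positive"]
  se <- sqrt(rate * (1 - rate) / nrow(resp))
  expect_lt(abs(mean(tap$tap_positive) - rate), 3 * se)
})

test_that("latent correlation induces dependence while preserving marginals", {
  cfg0 <- simulation_config()
  vars <- c(cfg0$continuous$var, cfg0$binary$var)
  rho <- diag(length(vars)); dimnames(rho) <- list(vars, vars)
  rho["ca", "desh"] <- rho["desh", "ca"] <- -0.6
  cfg <- simulation_config(n_responders = 20000, n_non_responders = 10,
                           correlation = rho)
  resp <- dplyr::filter(simulate_cohort(cfg, seed = 5), outcome == "responder")
  expect_lt(cor(resp$ca, as.numeric(resp$desh)), -0.3)
  expect_equal(mean(resp$ca), 71.21, tolerance = 0.02)

  rho["ca", "desh"] <- rho["desh", "ca"] <- 1.5  # not positive definite
  expect_error(simulation_config(correlation = rho), "positive definite")
})

test_that("reconstruction finds exactly the solutions the brute-force oracle finds", {
  targets <- table_targets()
  recon <- reconstruct_joint_tables(targets)

  oracle_resp <- brute_force_tables(96, 61, 53, group_targets(targets, "responders"),
                                    sens = TRUE)
  expect_true(recon$responders$exact)
  expect_equal(nrow(recon$responders$solutions), nrow(oracle_resp))
  got <- dplyr::arrange(recon$responders$solutions, n111)
  ora <- oracle_resp[order(oracle_resp$n111), ]
  for (cn in names(got)) expect_equal(got[[cn]], ora[[cn]])

  # non-responder group: the oracle confirms no exact integer table exists
  oracle_non <- brute_force_tables(70, 28, 8, group_targets(targets, "non_responders"),
                                   sens = FALSE)
  expect_null(oracle_non)
  expect_false(recon$non_responders$exact)
  expect_gt(nrow(recon$non_responders$solutions), 0)
  # and the solver's fallback deviation is minimal per the oracle at widened tol
  wide <- brute_force_tables(70, 28, 8, group_targets(targets, "non_responders"),
                             sens = FALSE, tol = recon$non_responders$max_abs_deviation + 1e-9)
  expect_equal(min(wide$dev), recon$non_responders$max_abs_deviation)
  expect_true(any(abs(wide$dev - recon$non_responders$max_abs_deviation) < 1e-12))
  # the finding is surfaced in the report notes
  expect_true(any(grepl("no integer table", recon$notes)))
  expect_true(any(grepl("exact integer table", recon$notes)))
})

test_that("fewer constraints cannot shrink the solution set", {
  # a small group where both constraint sets are exactly satisfiable
  full <- list(
    group_sizes = list(responders = 10, non_responders = 8),
    tap_positive = list(responders = 4, non_responders = 3),
    desh_positive = list(responders = 3, non_responders = 2),
    table4 = list(
      tap = list(sensitivity = 0.4, specificity = 0.625),
      desh = list(sensitivity = 0.3, specificity = 0.75),
      ca = list(sensitivity = 0.5, specificity = 0.5),
      tap_desh = list(sensitivity = 0.5, specificity = 0.5),
      tap_ca = list(sensitivity = 0.7, specificity = 0.375),
      majority = list(sensitivity = 0.4, specificity = 0.625)
    ),
    ca_cutoff = 68.7
  )
  marker_only <- full
  marker_only$table4$tap_desh <- NULL
  marker_only$table4$tap_ca <- NULL
  marker_only$table4$majority <- NULL

  r_full <- reconstruct_joint_tables(full)
  r_loose <- reconstruct_joint_tables(marker_only)
  expect_true(r_full$responders$exact)
  expect_true(r_loose$responders$exact)
  expect_gt(nrow(r_loose$responders$solutions), 1)
  expect_gte(nrow(r_loose$responders$solutions), nrow(r_full$responders$solutions))
  # every fully-constrained solution is also in the marker-only set
  key <- function(df) do.call(paste, df)
  expect_true(all(key(r_full$responders$solutions) %in% key(r_loose$responders$solutions)))
})

test_that("contradictory targets produce an infeasibility report, not an error", {
  targets <- table_targets()
  targets$tap_positive$responders <- 200  # union smaller than a margin
  recon <- reconstruct_joint_tables(targets)
  expect_false(recon$responders$exact)
  expect_equal(nrow(recon$responders$solutions), 0)
  expect_true(any(grepl("contradictory", recon$notes)))
})

test_that("fixture cohorts reproduce the reconstructed joint structure exactly", {
  recon <- reconstruct_joint_tables()
  fix <- build_fixture_cohort(recon, seed = 21)
  expect_equal(nrow(fix), 166)
  expect_identical(fix, build_fixture_cohort(recon, seed = 21))

  resp <- fix$outcome == "responder"
  tap <- classify_tap_response(fix)$tap_positive
  expect_equal(c(sum(tap & resp), sum(!tap & resp), sum(tap & !resp), sum(!tap & !resp)),
               c(61, 35, 28, 42))
  expect_equal(c(sum(fix$desh & resp), sum(fix$desh & !resp),
                 sum(!fix$desh & resp), sum(!fix$desh & !resp)),
               c(53, 8, 43, 62))

  # every accuracy row recomputed from the fixture equals the solver's derived metrics
  rules <- classify_cohort(fix, ca_cutoff = recon$targets$ca_cutoff)
  cols <- c(tap = "tap_positive", desh = "desh", ca = "ca_positive",
            tap_desh = "rule_tap_desh", tap_ca = "rule_tap_ca",
            majority = "rule_majority")
  derived <- recon$derived
  for (rule in names(cols)) {
    perf <- diagnostic_performance(confusion_counts(as.logical(rules[[cols[rule]]]), resp))
    expect_equal(perf$sensitivity, derived$sensitivity[derived$rule == rule])
    expect_equal(perf$specificity, derived$specificity[derived$rule == rule])
  }
})
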