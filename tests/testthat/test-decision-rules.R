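tap_row <- function(pre_time = 20, post_time = 20, pre_steps = 30, post_steps = 30,
                    pre_mmse = 20, post_mmse = 20, pre_uri = 5, post_uri = 5) {
  tibble::tibble(
    pre_walk_time = pre_time, post_walk_time = post_time,
    pre_walk_steps = pre_steps, post_walk_steps = post_steps,
    pre_mmse = pre_mmse, post_mmse = post_mmse,
    pre_urinary = pre_uri, post_urinary = post_uri
  )
}

test_that("tap positivity requires at least one criterion, boundaries inclusive", {
  r <- classify_tap_response(tap_row(pre_time = 20, post_time = 15))
  expect_true(r$tap_positive && r$crit_gait && !r$crit_cognitive && !r$crit_urinary)

  r <- classify_tap_response(tap_row(pre_mmse = 20, post_mmse = 22))  # exactly 10%
  expect_true(r$tap_positive && r$crit_cognitive && !r$crit_gait)

  r <- classify_tap_response(tap_row(pre_time = 20, post_time = 17,
                                     pre_mmse = 20, post_mmse = 21))
  expect_false(r$tap_positive)
  expect_false(any(r$crit_gait, r$crit_cognitive, r$crit_urinary))

  r <- classify_tap_response(tap_row(pre_uri = 5, post_uri = 4))
  expect_true(r$tap_positive && r$crit_urinary)

  # steps alone suffice for the gait criterion (exactly 20%)
  r <- classify_tap_response(tap_row(pre_steps = 30, post_steps = 24))
  expect_true(r$tap_positive && r$crit_gait)
})

test_that("degenerate pre-tap values: MMSE 0 is flagged, walk zero errors", {
  r <- classify_tap_response(tap_row(pre_mmse = 0, post_mmse = 5))
  expect_false(r$crit_cognitive)
  expect_true(r$mmse_unevaluable)
  expect_error(classify_tap_response(tap_row(pre_time = 0)), "positive")
})

test_that("tap classification is monotone in each improvement margin", {
  base <- tap_row()
  last <- -Inf
  for (post in seq(20, 10, by = -0.5)) {
    r <- classify_tap_response(tap_row(post_time = post))
    impr <- (20 - post) / 20
    if (r$tap_positive) expect_gte(impr, 0.20)
    if (impr >= 0.20) expect_true(r$tap_positive)
  }
})

test_that("Krauss responder rule: inclusive 0.5 boundary, scale invariant", {
  d <- tibble::tibble(preop_severity = c(10, 10, 10), postop_severity = c(5, 10, 6))
  r <- krauss_responder(d)
  expect_equal(r$krauss_index, c(0.5, 0.0, 0.4))
  expect_identical(r$responder, c(TRUE, FALSE, FALSE))
  r2 <- krauss_responder(dplyr::mutate(d, preop_severity = preop_severity * 7,
                                       postop_severity = postop_severity * 7))
  expect_equal(r2$krauss_index, r$krauss_index)
  expect_error(krauss_responder(tibble::tibble(preop_severity = 0, postop_severity = 0)),
               "positive")
})

test_that("CA dichotomization is inclusive at the cutoff with a strict switch", {
  expect_true(dichotomize_ca(60.0, 68.7))
  expect_true(dichotomize_ca(68.7, 68.7))
  expect_false(dichotomize_ca(68.7, 68.7, inclusive = FALSE))
  expect_false(dichotomize_ca(76.0, 68.7))  # non-responder mean falls negative
  expect_error(dichotomize_ca(190, 68.7), "0, 180")
})

test_that("OR combination upgrades tap-negatives and is monotone", {
  expect_true(combine_or(FALSE, TRUE))
  expect_false(combine_or(FALSE, FALSE))
  expect_true(combine_or(TRUE, FALSE))
  for (t in c(FALSE, TRUE)) for (i in c(FALSE, TRUE)) {
    expect_gte(combine_or(t, TRUE), combine_or(t, i))
    expect_gte(combine_or(TRUE, i), combine_or(t, i))
  }
})

test_that("tap override rule equals 2-of-3 majority on all 8 assignments", {
  grid <- expand.grid(t = c(FALSE, TRUE), d = c(FALSE, TRUE), c = c(FALSE, TRUE))
  got <- combine_majority(grid$t, grid$d, grid$c)
  expect_identical(got, (grid$t + grid$d + grid$c) >= 2)
  # the two published override clauses
  expect_false(combine_majority(TRUE, FALSE, FALSE))
  expect_true(combine_majority(FALSE, TRUE, TRUE))
  expect_true(combine_majority(TRUE, TRUE, FALSE))
})
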