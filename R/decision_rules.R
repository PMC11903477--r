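#' Tap-test positivity criteria
#'
#' Thresholds for calling a CSF tap test positive. Defaults follow the
#' Japanese iNPH guideline convention: at least a 20% improvement in time or
#' steps of the 10 m walk, and/or at least a 10% relative improvement in
#' MMSE, and/or an improvement of at least 1 point on the 0-10 urinary
#' severity scale. All boundaries are inclusive.
#'
#' @param gait_improvement_threshold Relative improvement in walk time or
#'   steps required for the gait criterion (fraction, default 0.20).
#' @param mmse_improvement_threshold Relative MMSE improvement required for
#'   the cognition criterion (fraction, default 0.10).
#' @param urinary_improvement_points Absolute drop in urinary severity
#'   required for the urinary criterion (points, default 1).
#' @return An object of class `tap_criteria`.
#' @export
tap_criteria <- function(gait_improvement_threshold = 0.20,
                         mmse_improvement_threshold = 0.10,
                         urinary_improvement_points = 1L) {
  if (gait_improvement_threshold <= 0 || mmse_improvement_threshold <= 0 ||
      urinary_improvement_points <= 0) {
    abort_domain("tap criteria thresholds must be positive")
  }
  structure(
    list(gait_improvement_threshold = gait_improvement_threshold,
         mmse_improvement_threshold = mmse_improvement_threshold,
         urinary_improvement_points = urinary_improvement_points),
    class = "tap_criteria"
  )
}

#' Classify tap-test response
#'
#' Applies the three positivity criteria to paired pre/post tap assessments.
#' Gait improvement is the relative decrease `(pre - post)/pre` in walk time
#' or step count (either suffices); cognitive improvement is the relative
#' increase `(post - pre)/pre` in MMSE; urinary improvement is an absolute
#' decrease `pre - post` in the 0-10 severity score. A subject is tap
#' positive if at least one criterion is met. A pre-tap MMSE of 0 makes the
#' relative cognitive change undefined; that criterion is then treated as
#' not met and the subject is flagged.
#'
#' @param data Data frame with columns `pre_walk_time`, `pre_walk_steps`,
#'   `pre_mmse`, `pre_urinary`, `post_walk_time`, `post_walk_steps`,
#'   `post_mmse`, `post_urinary` (a cohort tibble works directly).
#' @param criteria A [tap_criteria()] object.
#' @return The input tibble with logical columns `crit_gait`,
#'   `crit_cognitive`, `crit_urinary`, `tap_positive` and
#'   `mmse_unevaluable` appended.
#' @export
classify_tap_response <- function(data, criteria = tap_criteria()) {
  stopifnot(inherits(criteria, "tap_criteria"))
  need <- c("pre_walk_time", "pre_walk_steps", "pre_mmse", "pre_urinary",
            "post_walk_time", "post_walk_steps", "post_mmse", "post_urinary")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    abort_domain(sprintf("missing tap assessment column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (any(data$pre_walk_time <= 0, na.rm = TRUE) ||
      any(data$pre_walk_steps <= 0, na.rm = TRUE)) {
    abort_domain("pre-tap walk time and steps must be positive")
  }
  g <- criteria$gait_improvement_threshold
  m <- criteria$mmse_improvement_threshold
  u <- criteria$urinary_improvement_points
  dplyr::mutate(
    tibble::as_tibble(data),
    crit_gait = (.data$pre_walk_time - .data$post_walk_time) / .data$pre_walk_time >= g |
      (.data$pre_walk_steps - .data$post_walk_steps) / .data$pre_walk_steps >= g,
    mmse_unevaluable = .data$pre_mmse == 0 & .data$post_mmse != .data$pre_mmse,
    crit_cognitive = dplyr::if_else(
      .data$pre_mmse == 0, FALSE,
      (.data$post_mmse - .data$pre_mmse) / .data$pre_mmse >= m
    ),
    crit_urinary = (.data$pre_urinary - .data$post_urinary) >= u,
    tap_positive = .data$crit_gait | .data$crit_cognitive | .data$crit_urinary
  )
}

#' Krauss-index responder rule
#'
#' The Krauss index is the relative improvement of a pre/post symptom
#' severity score, `(preop - postop)/preop`; shunt responders are subjects
#' with index at or above the threshold (default 0.5, boundary inclusive).
#'
#' @param data Data frame with columns `preop_severity` and
#'   `postop_severity` (nonnegative ordinals, preop > 0).
#' @param responder_threshold Krauss-index cut for responder status,
#'   in (0, 1] (default 0.5).
#' @param score_fn Optional replacement scoring hook: a
#'   `function(preop, postop)` returning the improvement index. Defaults to
#'   the relative-improvement formula above.
#' @return The input tibble with `krauss_index` (numeric) and `responder`
#'   (logical) appended.
#' @export
krauss_responder <- function(data, responder_threshold = 0.5, score_fn = NULL) {
  if (responder_threshold <= 0 || responder_threshold > 1) {
    abort_domain("responder threshold must be in (0, 1]")
  }
  if (any(data$preop_severity <= 0, na.rm = TRUE)) {
    abort_domain("preoperative severity must be positive (no improvement is definable from 0)")
  }
  if (any(data$postop_severity < 0, na.rm = TRUE)) {
    abort_domain("postoperative severity must be nonnegative")
  }
  score_fn <- score_fn %||% function(preop, postop) (preop - postop) / preop
  dplyr::mutate(
    tibble::as_tibble(data),
    krauss_index = score_fn(.data$preop_severity, .data$postop_severity),
    responder = .data$krauss_index >= responder_threshold
  )
}

#' Dichotomize the callosal angle
#'
#' A smaller callosal angle predicts shunt response, so the test is positive
#' when the angle is at or below the cutoff. The boundary is inclusive
#' (`ca == cutoff` is positive) by default so the reported optimal cutoff is
#' classified with the group it was selected to capture; set
#' `inclusive = FALSE` for a strict comparison.
#'
#' @param ca Callosal angle(s) in degrees, in (0, 180).
#' @param cutoff Cut point in degrees, in (0, 180). The cutoff reported for
#'   shunt-outcome prediction in iNPH is 68.7.
#' @param inclusive Logical: is the boundary counted as positive?
#' @return Logical vector: `TRUE` where the angle is on the positive
#'   (response-predicting) side.
#' @export
dichotomize_ca <- function(ca, cutoff = 68.7, inclusive = TRUE) {
  ok <- function(x) all(is.na(x) | (x > 0 & x < 180))
  if (!ok(ca) || !ok(cutoff)) abort_domain("angles must be in (0, 180) degrees")
  if (inclusive) ca <= cutoff else ca < cutoff
}

#' Believe-the-positive (OR) combination of two binary tests
#'
#' A tap-negative subject with a positive imaging marker is upgraded to
#' combined-positive; a tap-positive subject stays positive. This is the
#' logical OR and is used for both tap+DESH and tap+CA combinations.
#'
#' @param tap_positive,imaging_positive Logical vectors.
#' @return Logical vector, the elementwise OR.
#' @export
combine_or <- function(tap_positive, imaging_positive) {
  tap_positive | imaging_positive
}

#' Tap test overridden by concordant imaging (majority rule)
#'
#' Starts from the tap result and overrides it only when both imaging
#' markers disagree with it: a tap-positive subject with negative DESH and
#' negative CA becomes negative; a tap-negative subject with positive DESH
#' and positive CA becomes positive. Equivalent to a 2-of-3 majority vote
#' over (tap, DESH, CA).
#'
#' @param tap_positive,desh_positive,ca_positive Logical vectors.
#' @return Logical vector, the combined prediction.
#' @export
combine_majority <- function(tap_positive, desh_positive, ca_positive) {
  dplyr::case_when(
    tap_positive & !desh_positive & !ca_positive ~ FALSE,
    !tap_positive & desh_positive & ca_positive ~ TRUE,
    .default = tap_positive
  )
}

#' Per-patient rule outputs for a cohort
#'
#' Convenience wrapper running the tap classification, CA dichotomization
#' and both combination rules over a cohort, yielding the per-patient binary
#' predictions evaluated in the accuracy tables.
#'
#' @param cohort A cohort tibble with tap assessment and imaging columns.
#' @param criteria A [tap_criteria()] object.
#' @param ca_cutoff Callosal angle cut point in degrees.
#' @return The cohort with `tap_positive`, `ca_positive`, `rule_tap_desh`,
#'   `rule_tap_ca`, `rule_majority` columns appended (plus the per-criterion
#'   tap columns).
#' @export
classify_cohort <- function(cohort, criteria = tap_criteria(), ca_cutoff = 68.7) {
  out <- classify_tap_response(cohort, criteria)
  dplyr::mutate(
    out,
    ca_positive = dichotomize_ca(.data$ca, ca_cutoff),
    rule_tap_desh = combine_or(.data$tap_positive, .data$desh),
    rule_tap_ca = combine_or(.data$tap_positive, .data$ca_positive),
    rule_majority = combine_majority(.data$tap_positive, .data$desh, .data$ca_positive)
  )
}
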