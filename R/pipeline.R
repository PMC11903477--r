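#' Analysis configuration for the full pipeline
#'
#' @param tap A [tap_criteria()] object for tap-test positivity.
#' @param responder_threshold Krauss-index threshold defining responders.
#' @param alpha Gate level for the normality/variance dispatch in the
#'   group comparisons.
#' @param entry_alpha,removal_alpha Forward-LR selection thresholds.
#' @param ca_cutoff Callosal angle cut point in degrees, or `NULL`
#'   (default) to re-estimate it on the analyzed cohort by the Youden
#'   index. Fixture reproduction pins the published 68.7; simulations
#'   typically re-estimate.
#' @return An `analysis_config` object.
#' @export
analysis_config <- function(tap = tap_criteria(), responder_threshold = 0.5,
                            alpha = 0.05, entry_alpha = 0.05,
                            removal_alpha = 0.10, ca_cutoff = NULL) {
  structure(
    list(tap = tap, responder_threshold = responder_threshold, alpha = alpha,
         entry_alpha = entry_alpha, removal_alpha = removal_alpha,
         ca_cutoff = ca_cutoff),
    class = "analysis_config"
  )
}

table1_spec <- function() {
  list(
    continuous = c("age", "lp_pressure", "disease_duration"),
    categorical = c("sex_male", "tap_positive", "sym_gait", "sym_cognitive",
                    "sym_urinary", "com_cardiovascular", "com_endocrine",
                    "com_neurological")
  )
}

table2_spec <- function() {
  list(
    continuous = c("ei", "ca", "z_ei", "bvr", "scca", "temporal_horn_left",
                   "temporal_horn_right", "third_ventricle_width",
                   "posterior_horn_ratio"),
    categorical = "desh"
  )
}

compare_block <- function(data, spec, responder, alpha) {
  cont <- purrr::map_dfr(spec$continuous, function(v) {
    x <- data[[v]]
    compare_continuous(x[responder], x[!responder], alpha = alpha, variable = v)
  })
  cat_ <- purrr::map_dfr(spec$categorical, function(v) {
    x <- as.logical(data[[v]])
    tab <- matrix(c(sum(x & responder, na.rm = TRUE),
                    sum(x & !responder, na.rm = TRUE),
                    sum(!x & responder, na.rm = TRUE),
                    sum(!x & !responder, na.rm = TRUE)),
                  nrow = 2, byrow = TRUE)
    chi_square_test(tab, variable = v)
  })
  dplyr::bind_rows(cont, cat_)
}

label_outcomes <- function(cohort, config) {
  have_sev <- all(c("preop_severity", "postop_severity") %in% names(cohort)) &&
    !all(is.na(cohort$preop_severity))
  if (have_sev) {
    labeled <- krauss_responder(cohort, responder_threshold = config$responder_threshold)
    labeled$responder
  } else if ("outcome" %in% names(cohort) && !all(is.na(cohort$outcome))) {
    cohort$outcome == "responder"
  } else {
    abort_domain("cohort has neither severity scores nor outcome labels")
  }
}

#' Run the complete shunt-response analysis on a cohort
#'
#' Executes, in order: outcome labeling by the Krauss rule; the demographic
#' and imaging group-comparison tables (t-test / Mann-Whitney dispatch for
#' continuous variables, chi-square for categorical); the forward-LR
#' multivariable logistic regression on Evans index, DESH and callosal
#' angle; Youden-index cutoff selection for the callosal angle;
#' dichotomization; and the diagnostic accuracy table for the six
#' prediction rules (tap, DESH, CA, tap+DESH, tap+CA, tap overridden by
#' concordant imaging). Deterministic given cohort and configuration.
#'
#' @param cohort A cohort tibble (see [cohort_schema()]).
#' @param config An [analysis_config()] object.
#' @return A `shunt_report` object: list with `table1`, `table2` (tibbles of
#'   group comparisons), `table3` (a `forward_lr_fit`), `youden` (a
#'   `shunt_roc` for the callosal angle), `ca_cutoff_used`, `table4`
#'   (tibble: rule, confusion cells, raw and 2-dp metrics), `exclusions`,
#'   and `provenance`.
#' @export
run_full_analysis <- function(cohort, config = analysis_config()) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- tibble::as_tibble(cohort)
  responder <- label_outcomes(cohort, config)
  if (length(unique(responder[!is.na(responder)])) < 2) {
    abort_domain("cohort must contain both responders and non-responders")
  }
  exclusions <- list(outcome_missing = sum(is.na(responder)))
  keep <- !is.na(responder)
  cohort <- cohort[keep, ]
  responder <- responder[keep]
  data <- dplyr::mutate(cohort, sex_male = .data$sex == "male")
  data <- classify_tap_response(data, config$tap)

  table1 <- compare_block(data, table1_spec(), responder, config$alpha)
  table2 <- compare_block(data, table2_spec(), responder, config$alpha)

  model_data <- dplyr::mutate(data, responder = as.integer(responder),
                              desh = as.numeric(.data$desh))
  table3 <- fit_logistic_forward_lr(
    model_data, outcome = "responder", candidates = c("ei", "desh", "ca"),
    entry_alpha = config$entry_alpha, removal_alpha = config$removal_alpha
  )

  youden <- roc_youden(data$ca, responder, direction = "lower_is_positive")
  cutoff <- config$ca_cutoff %||% youden$optimal_cutoff
  if (is.na(cutoff)) abort_domain("callosal angle cutoff is undefined and none was configured")

  rules <- classify_cohort(data, criteria = config$tap, ca_cutoff = cutoff)
  rule_cols <- c(tap = "tap_positive", desh = "desh", ca = "ca_positive",
                 tap_desh = "rule_tap_desh", tap_ca = "rule_tap_ca",
                 majority = "rule_majority")
  table4 <- purrr::imap_dfr(rule_cols, function(col, rule) {
    perf <- diagnostic_performance(confusion_counts(as.logical(rules[[col]]), responder))
    dplyr::bind_cols(tibble::tibble(rule = rule), perf)
  })

  provenance <- list(
    package_version = as.character(utils::packageVersion("shuntpredict")),
    n_subjects = nrow(cohort),
    config_hash = fnv1a_hash(paste(deparse(config), collapse = "")),
    cohort_hash = fnv1a_hash(paste(utils::capture.output(
      utils::write.csv(as.data.frame(cohort), row.names = FALSE)), collapse = "\n"))
  )
  structure(
    list(table1 = table1, table2 = table2, table3 = table3, youden = youden,
         ca_cutoff_used = cutoff, table4 = table4, exclusions = exclusions,
         provenance = provenance),
    class = "shunt_report"
  )
}

#' @export
print.shunt_report <- function(x, ...) {
  cat("Shunt-response analysis report (n =", x$provenance$n_subjects, ")\n")
  cat("Callosal angle cutoff used:", format(x$ca_cutoff_used, digits = 4), "degrees\n")
  cat("\nDiagnostic accuracy of the prediction rules:\n")
  print(dplyr::select(x$table4, "rule", "sensitivity_2dp", "specificity_2dp", "auc_2dp"))
  invisible(x)
}

#' @export
tidy.shunt_report <- function(x, ...) x$table4

#' @export
glance.shunt_report <- function(x, ...) {
  tibble::tibble(
    n = x$provenance$n_subjects,
    ca_cutoff_used = x$ca_cutoff_used,
    ca_auc = x$youden$auc,
    n_selected = length(x$table3$selected),
    tap_p_value = x$table1$p_value[x$table1$variable == "tap_positive"]
  )
}

#' Serialize a report to deterministic JSON
#'
#' Identical inputs and configuration yield byte-identical JSON (no
#' timestamps, fixed key order, fixed precision-free number formatting).
#'
#' @param report A `shunt_report`.
#' @param path Optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to `path`).
#' @export
report_json <- function(report, path = NULL) {
  stopifnot(inherits(report, "shunt_report"))
  payload <- list(
    provenance = report$provenance,
    ca_cutoff_used = report$ca_cutoff_used,
    youden = as.list(glance(report$youden)),
    table1 = report$table1,
    table2 = report$table2,
    table3 = list(selected = report$table3$selected,
                  coefficients = report$table3$coefficients,
                  trace = report$table3$trace,
                  event_level = report$table3$event_level),
    table4 = report$table4,
    exclusions = report$exclusions
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, na = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}

#' Leave-one-center-out sensitivity analysis
#'
#' Sequentially excludes each recruiting center and reruns the full
#' analysis on the remaining subjects. Stage errors inside a reanalysis
#' (e.g. separation after removing a center that holds all DESH-positive
#' subjects) are captured per report rather than aborting the sweep.
#'
#' @param cohort A cohort tibble with at least two distinct `center_id`
#'   values.
#' @param config An [analysis_config()].
#' @return A `loco_result`: named list (one element per excluded center) of
#'   either `shunt_report` objects or condition objects, with a `summary`
#'   tibble attribute (excluded center, n, responders, non-responders,
#'   tap-positive count, DESH-positive count, mean CA, error flag).
#' @export
leave_one_center_out <- function(cohort, config = analysis_config()) {
  centers <- sort(unique(cohort$center_id))
  if (length(centers) < 2) abort_domain("leave-one-center-out needs at least 2 centers")
  reports <- purrr::map(centers, function(ctr) {
    sub <- cohort[cohort$center_id != ctr, ]
    tryCatch(run_full_analysis(sub, config), error = function(e) e)
  })
  names(reports) <- centers
  summary <- purrr::map_dfr(centers, function(ctr) {
    sub <- cohort[cohort$center_id != ctr, ]
    resp <- tryCatch(label_outcomes(sub, config), error = function(e) rep(NA, nrow(sub)))
    tap <- tryCatch(classify_tap_response(sub, config$tap)$tap_positive,
                    error = function(e) rep(NA, nrow(sub)))
    tibble::tibble(
      excluded_center = ctr, n = nrow(sub),
      responders = sum(resp, na.rm = TRUE),
      non_responders = sum(!resp, na.rm = TRUE),
      tap_positive = sum(tap, na.rm = TRUE),
      desh_positive = sum(sub$desh, na.rm = TRUE),
      mean_ei = mean(sub$ei, na.rm = TRUE),
      mean_ca = mean(sub$ca, na.rm = TRUE),
      error = inherits(reports[[ctr]], "condition")
    )
  })
  structure(reports, class = "loco_result", summary = summary)
}

#' @export
print.loco_result <- function(x, ...) {
  cat("Leave-one-center-out sensitivity analysis:\n")
  print(attr(x, "summary"))
  invisible(x)
}

#' @export
tidy.loco_result <- function(x, ...) attr(x, "summary")

#' Plot the diagnostic accuracy table of a report
#'
#' Dot plot of sensitivity, specificity and AUC per prediction rule.
#'
#' @param object A `shunt_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shunt_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    dplyr::select(object$table4, "rule", "sensitivity", "specificity", "auc"),
    cols = c("sensitivity", "specificity", "auc"),
    names_to = "metric", values_to = "value"
  )
  long$rule <- factor(long$rule, levels = rev(unique(object$table4$rule)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value, y = .data$rule,
                                     colour = .data$metric)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL, colour = NULL,
                  title = "Diagnostic accuracy of the prediction rules") +
    ggplot2::theme_minimal()
}
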