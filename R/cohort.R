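#' @importFrom rlang .data
NULL

#' Cohort column schema
#'
#' One row per column of a patient-level cohort table: the column name, its
#' storage type, physical unit (or code set) and whether the column is
#' required. Patients are rows; a cohort is an ordinary tibble, so every
#' verb in dplyr works on it directly. Booleans are serialized to CSV as
#' 0/1; the optional `outcome` column uses the codes `responder` /
#' `non_responder` and may be empty before follow-up.
#'
#' @return A tibble with columns `column`, `type` (`"character"`,
#'   `"numeric"`, `"integer"`, `"logical"`), `unit`, `required`.
#' @examples
#' cohort_schema()
#' @export
cohort_schema <- function() {
  tribble_row <- function(column, type, unit, required = TRUE) {
    tibble::tibble(column = column, type = type, unit = unit, required = required)
  }
  dplyr::bind_rows(
    tribble_row("id", "character", "subject identifier"),
    tribble_row("center_id", "character", "recruiting center code"),
    tribble_row("age", "numeric", "years"),
    tribble_row("sex", "character", "male/female"),
    tribble_row("lp_pressure", "numeric", "mmH2O"),
    tribble_row("disease_duration", "numeric", "months"),
    tribble_row("sym_gait", "logical", "gait disturbance present"),
    tribble_row("sym_cognitive", "logical", "cognitive impairment present"),
    tribble_row("sym_urinary", "logical", "urinary dysfunction present"),
    tribble_row("com_cardiovascular", "logical", "cardiovascular comorbidity"),
    tribble_row("com_endocrine", "logical", "endocrine comorbidity"),
    tribble_row("com_neurological", "logical", "neurological comorbidity"),
    tribble_row("pre_walk_time", "numeric", "seconds, 10 m walk before tap"),
    tribble_row("pre_walk_steps", "integer", "steps, 10 m walk before tap"),
    tribble_row("pre_mmse", "integer", "MMSE 0-30 before tap"),
    tribble_row("pre_urinary", "integer", "urinary severity 0-10 before tap"),
    tribble_row("post_walk_time", "numeric", "seconds, 10 m walk after tap"),
    tribble_row("post_walk_steps", "integer", "steps, 10 m walk after tap"),
    tribble_row("post_mmse", "integer", "MMSE 0-30 after tap"),
    tribble_row("post_urinary", "integer", "urinary severity 0-10 after tap"),
    tribble_row("ei", "numeric", "Evans index (ratio)"),
    tribble_row("desh", "logical", "DESH sign on MRI"),
    tribble_row("ca", "numeric", "callosal angle, degrees"),
    tribble_row("z_ei", "numeric", "z-Evans index (ratio)"),
    tribble_row("bvr", "numeric", "brain-per-ventricle ratio"),
    tribble_row("scca", "numeric", "splenium corpus callosum angle, degrees"),
    tribble_row("temporal_horn_left", "numeric", "mm"),
    tribble_row("temporal_horn_right", "numeric", "mm"),
    tribble_row("third_ventricle_width", "numeric", "mm"),
    tribble_row("posterior_horn_ratio", "numeric", "posterior horn ratio"),
    tribble_row("preop_severity", "integer", "symptom severity score, preop"),
    tribble_row("postop_severity", "integer", "symptom severity score, postop"),
    tribble_row("outcome", "character", "responder/non_responder", required = FALSE)
  )
}

cohort_col_types <- function() {
  sch <- cohort_schema()
  # doubles are read as text and converted with strtod (correctly rounded),
  # so a 17-significant-digit serialization round-trips bit-exactly
  codes <- c(character = "c", numeric = "c", integer = "i", logical = "i")
  stats::setNames(unname(codes[sch$type]), sch$column)
}

logical_cols <- function() {
  sch <- cohort_schema()
  sch$column[sch$type == "logical"]
}

#' Read a patient-level cohort from CSV
#'
#' Reads a cohort table written by [write_cohort_csv()] (comma separated,
#' UTF-8, dot decimal, header required, booleans coded 0/1). Columns are
#' checked against [cohort_schema()]; missing required columns are an error
#' naming the column. Validation of field-level invariants is separate and
#' total: run [validate_cohort()] on the result.
#'
#' @param path Path to a cohort CSV file.
#' @param validate If `TRUE` (default), run [validate_cohort()] on the parsed
#'   table and raise an error naming the first offending row and field.
#'   Use `validate = FALSE` to obtain the raw table together with its
#'   violation list.
#' @return A cohort tibble, one row per patient, in file order.
#' @seealso [write_cohort_csv()], [validate_cohort()]
#' @export
read_cohort_csv <- function(path, validate = TRUE) {
  if (!file.exists(path)) abort_domain(sprintf("cohort file not found: %s", path))
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               name_repair = "minimal"))
  sch <- cohort_schema()
  missing <- setdiff(sch$column[sch$required], hdr)
  if (length(missing) > 0) {
    abort_domain(sprintf("cohort CSV is missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  types <- cohort_col_types()
  spec <- do.call(readr::cols, c(as.list(types[intersect(names(types), hdr)]),
                                 list(.default = readr::col_guess())))
  df <- readr::read_csv(path, col_types = spec, show_col_types = FALSE,
                        progress = FALSE)
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    p <- probs[1, ]
    abort_domain(sprintf("unparseable cell at data row %d, column %d: expected %s",
                         p$row, p$col, p$expected))
  }
  sch_num <- cohort_schema()
  for (col in sch_num$column[sch_num$type == "numeric"]) {
    if (!col %in% names(df)) next
    x <- df[[col]]
    bad <- which(!is.na(x) & is.na(suppressWarnings(as.numeric(x))))
    if (length(bad) > 0) {
      abort_domain(sprintf("unparseable cell at data row %d, column `%s`: %s",
                           bad[1], col, x[bad[1]]))
    }
    df[[col]] <- as.numeric(x)
  }
  for (col in intersect(logical_cols(), names(df))) {
    bad <- which(!(df[[col]] %in% c(0L, 1L, NA_integer_)))
    if (length(bad) > 0) {
      abort_domain(sprintf("column `%s` must be coded 0/1; data row %d is %s",
                           col, bad[1], df[[col]][bad[1]]))
    }
    df[[col]] <- as.logical(df[[col]])
  }
  if (!"outcome" %in% names(df)) df$outcome <- NA_character_
  df <- df[, cohort_schema()$column]
  if (validate) {
    v <- validate_cohort(df)
    if (nrow(v) > 0) {
      abort_domain(sprintf("invalid cohort: row %d, field `%s`: %s (value %s)",
                           v$row[1], v$field[1], v$rule[1], v$value[1]))
    }
  }
  df
}

#' Write a patient-level cohort to CSV
#'
#' Deterministic column order (that of [cohort_schema()]), UTF-8, dot
#' decimal, booleans as 0/1 and missing values as empty cells, so that
#' `read_cohort_csv(write_cohort_csv(x))` reproduces `x` field for field and
#' repeated writes of the same cohort are byte identical.
#'
#' @param cohort A cohort tibble (see [cohort_schema()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  sch <- cohort_schema()
  missing <- setdiff(sch$column[sch$required], names(cohort))
  if (length(missing) > 0) {
    abort_domain(sprintf("cohort is missing required column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  if (!"outcome" %in% names(cohort)) cohort$outcome <- NA_character_
  out <- cohort[, sch$column]
  for (col in logical_cols()) out[[col]] <- as.integer(out[[col]])
  # serialize doubles at 17 significant digits so read-back is bit-exact
  for (col in sch$column[sch$type == "numeric"]) {
    x <- out[[col]]
    out[[col]] <- ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  }
  readr::write_csv(out, path, na = "", progress = FALSE)
  invisible(path)
}

#' Validate a cohort against its field invariants
#'
#' Validation is total: every row yields a (possibly empty) set of
#' violations, never an error. Checked invariants: age > 0; lumbar puncture
#' pressure within the 80-200 mmH2O inclusion window; disease duration > 0;
#' walk times/steps > 0; MMSE in 0-30; urinary score in 0-10; Evans index
#' and the other ratios in their domains; angles in (0, 180); widths >= 0;
#' severity scores >= 0; sex and outcome codes from their code sets.
#'
#' @param cohort A cohort tibble.
#' @return A tibble of violations with columns `row`, `id`, `field`, `rule`,
#'   `value`; zero rows when the cohort is clean. Missing optional values are
#'   not violations.
#' @export
validate_cohort <- function(cohort) {
  n <- nrow(cohort)
  viol <- list()
  add <- function(rows, field, rule) {
    rows <- rows[!is.na(rows)]
    if (length(rows) == 0) return()
    viol[[length(viol) + 1]] <<- tibble::tibble(
      row = rows,
      id = as.character(cohort$id[rows]),
      field = field,
      rule = rule,
      value = as.character(cohort[[field]][rows])
    )
  }
  bad <- function(col, test) {
    x <- cohort[[col]]
    which(!is.na(x) & !test(x))
  }
  add(bad("age", function(x) x > 0), "age", "age must be > 0")
  add(bad("lp_pressure", function(x) x >= 80 & x <= 200),
      "lp_pressure", "lumbar puncture pressure must be in [80, 200] mmH2O")
  add(bad("disease_duration", function(x) x > 0),
      "disease_duration", "disease duration must be > 0 months")
  add(bad("sex", function(x) x %in% c("male", "female")),
      "sex", "sex must be 'male' or 'female'")
  for (col in c("pre_walk_time", "pre_walk_steps", "post_walk_time", "post_walk_steps")) {
    add(bad(col, function(x) x > 0), col, "walk measurements must be > 0")
  }
  for (col in c("pre_mmse", "post_mmse")) {
    add(bad(col, function(x) x >= 0 & x <= 30), col, "MMSE must be in [0, 30]")
  }
  for (col in c("pre_urinary", "post_urinary")) {
    add(bad(col, function(x) x >= 0 & x <= 10), col, "urinary score must be in [0, 10]")
  }
  add(bad("ei", function(x) x > 0 & x < 1), "ei", "Evans index must be in (0, 1)")
  for (col in c("ca", "scca")) {
    add(bad(col, function(x) x > 0 & x < 180), col, "angle must be in (0, 180) degrees")
  }
  for (col in c("z_ei", "bvr", "posterior_horn_ratio")) {
    add(bad(col, function(x) x >= 0), col, "ratio must be >= 0")
  }
  for (col in c("temporal_horn_left", "temporal_horn_right", "third_ventricle_width")) {
    add(bad(col, function(x) x >= 0), col, "width must be >= 0 mm")
  }
  for (col in c("preop_severity", "postop_severity")) {
    add(bad(col, function(x) x >= 0), col, "severity score must be >= 0")
  }
  add(bad("outcome", function(x) x %in% c("responder", "non_responder")),
      "outcome", "outcome must be 'responder' or 'non_responder'")
  if (length(viol) == 0) {
    return(tibble::tibble(row = integer(), id = character(), field = character(),
                          rule = character(), value = character()))
  }
  dplyr::arrange(dplyr::bind_rows(viol), .data$row, .data$field)
}
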