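#' Compare a continuous variable between two groups
#'
#' Implements the univariate dispatch used for the demographic and imaging
#' tables: within-group normality is assessed by the Shapiro-Wilk test and
#' homogeneity of variances by the two-sample variance-ratio F-test; when
#' both groups are compatible with normality and the variances are
#' homogeneous (all tests at `alpha`) a pooled-variance two-sample t-test is
#' used, otherwise the Mann-Whitney U test. The Mann-Whitney p-value uses
#' exact enumeration for small tie-free samples (both n < 8) and the
#' tie-corrected normal approximation (no continuity correction) otherwise.
#'
#' @param group_a,group_b Numeric vectors, each of length >= 3 (the
#'   Shapiro-Wilk test is undefined below that).
#' @param alpha Gate level for the normality and variance tests (default
#'   0.05).
#' @param variable Optional variable name carried into the result.
#' @return A one-row tibble: `variable`, `test_used` (`"t_test"` or
#'   `"mann_whitney"`), `statistic`, `p_value`, `mean_a`, `sd_a`, `mean_b`,
#'   `sd_b`, `n_a`, `n_b`.
#' @export
compare_continuous <- function(group_a, group_b, alpha = 0.05,
                               variable = NA_character_) {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 3 || length(group_b) < 3) {
    abort_domain("each group needs at least 3 non-missing values")
  }
  normal_ok <- function(x) {
    if (length(unique(x)) == 1) return(FALSE)  # degenerate: SW undefined
    stats::shapiro.test(x)$p.value >= alpha
  }
  gate <- normal_ok(group_a) && normal_ok(group_b) &&
    stats::var.test(group_a, group_b)$p.value >= alpha
  if (gate) {
    ht <- stats::t.test(group_a, group_b, var.equal = TRUE)
    used <- "t_test"
  } else {
    n_small <- length(group_a) < 8 && length(group_b) < 8
    has_ties <- anyDuplicated(c(group_a, group_b)) > 0
    ht <- suppressWarnings(stats::wilcox.test(
      group_a, group_b, exact = n_small && !has_ties, correct = FALSE
    ))
    used <- "mann_whitney"
  }
  tibble::tibble(
    variable = variable, test_used = used,
    statistic = unname(ht$statistic), p_value = ht$p.value,
    mean_a = mean(group_a), sd_a = stats::sd(group_a),
    mean_b = mean(group_b), sd_b = stats::sd(group_b),
    n_a = length(group_a), n_b = length(group_b)
  )
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' The intergroup test for categorical variables: Pearson's chi-square
#' without continuity correction, df = 1, two-sided.
#'
#' @param table A 2x2 matrix of counts (rows = category, columns = group) or
#'   a length-4 vector `c(a, b, c, d)` filled row-wise.
#' @param variable Optional variable name carried into the result.
#' @return A one-row tibble: `variable`, `test_used = "chi_square"`,
#'   `statistic`, `p_value`, the four cells `a`-`d` and the group-wise
#'   positive rates.
#' @export
chi_square_test <- function(table, variable = NA_character_) {
  if (is.numeric(table) && length(table) == 4) {
    table <- matrix(table, nrow = 2, byrow = TRUE)
  }
  if (!is.matrix(table) || !all(dim(table) == c(2, 2))) {
    abort_domain("`table` must be a 2x2 count matrix")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort_domain("chi-square test requires all row and column margins > 0")
  }
  ht <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  tibble::tibble(
    variable = variable, test_used = "chi_square",
    statistic = unname(ht$statistic), p_value = ht$p.value,
    a = table[1, 1], b = table[1, 2], c = table[2, 1], d = table[2, 2],
    rate_a = table[1, 1] / sum(table[, 1]), rate_b = table[1, 2] / sum(table[, 2])
  )
}

log_lik_binom <- function(fit) as.numeric(stats::logLik(fit))

fit_glm_checked <- function(formula, data) {
  fit <- suppressWarnings(
    stats::glm(formula, data = data, family = stats::binomial())
  )
  # separation: the fitted model classifies perfectly, with fitted
  # probabilities driven to the 0/1 boundary (coefficients diverging, SEs
  # exploding). glm converges quietly in this case, so test the fit itself.
  if (length(stats::coef(fit)) > 1) {
    p <- stats::fitted(fit)
    y <- fit$y
    eps <- 1e-5
    perfect <- length(unique(y)) == 2 &&
      max(p[y == 0]) < eps && min(p[y == 1]) > 1 - eps
    se <- sqrt(diag(stats::vcov(fit)))[-1]
    cf <- stats::coef(fit)[-1]
    quasi <- any(se > 100 & abs(cf) > 10 & abs(cf) / se < 1e-2)
    if (perfect || quasi) {
      abort_domain(sprintf(
        "separation detected while fitting %s: a covariate perfectly predicts the outcome",
        deparse(formula)
      ))
    }
  }
  if (!fit$converged) {
    abort_domain(sprintf("logistic fit did not converge for %s", deparse(formula)))
  }
  fit
}

#' Forward likelihood-ratio stepwise logistic regression
#'
#' Multivariable logistic regression with forward selection by likelihood
#' ratio: at each step the candidate whose addition gives the smallest
#' LR-test p-value (LR statistic = 2 * change in log-likelihood, df = 1)
#' enters if that p-value is below `entry_alpha`; after each entry, any
#' included variable whose removal LR p-value exceeds `removal_alpha` is
#' dropped. Fits are maximum likelihood via iteratively reweighted least
#' squares. Per-variable Wald chi-square is `(coef/se)^2` and the 95% CI for
#' the odds ratio is `exp(coef +/- 1.96 se)`. Perfect separation on a
#' candidate raises an explicit error.
#'
#' @param data Data frame holding the outcome and candidate columns.
#' @param outcome Name of a logical/0-1 outcome column. The modeled event is
#'   `outcome == TRUE`; odds ratios for the opposite coding are returned
#'   alongside (`odds_ratio_reversed = 1/odds_ratio`), since reported odds
#'   ratios depend on this (often unstated) choice.
#' @param candidates Character vector of candidate covariate column names.
#' @param entry_alpha LR p-value required to enter (default 0.05).
#' @param removal_alpha LR p-value above which an entered variable is
#'   removed (default 0.10).
#' @return A `forward_lr_fit` object: list with `fit` (the final `glm`),
#'   `selected` (character), `coefficients` tibble (term, estimate,
#'   std_error, wald_chi_square, p_value, odds_ratio, or ci bounds,
#'   odds_ratio_reversed), `trace` tibble (step, action, term, lr_statistic,
#'   p_value), `outcome`, `event_level`, `entry_alpha`, `removal_alpha`.
#' @export
fit_logistic_forward_lr <- function(data, outcome, candidates,
                                    entry_alpha = 0.05, removal_alpha = 0.10) {
  data <- tibble::as_tibble(data)
  if (!outcome %in% names(data)) abort_domain(sprintf("outcome column `%s` not found", outcome))
  missing <- setdiff(candidates, names(data))
  if (length(missing) > 0) {
    abort_domain(sprintf("candidate column(s) not found: %s", paste(missing, collapse = ", ")))
  }
  keep <- stats::complete.cases(data[, c(outcome, candidates)])
  data <- data[keep, ]
  y <- data[[outcome]]
  if (is.logical(y)) data[[outcome]] <- as.integer(y)
  if (length(unique(data[[outcome]])) < 2) abort_domain("outcome has a single class")

  model_formula <- function(terms) {
    rhs <- if (length(terms) == 0) "1" else paste(terms, collapse = " + ")
    stats::as.formula(paste(outcome, "~", rhs), env = environment())
  }
  selected <- character(0)
  current <- fit_glm_checked(model_formula(selected), data)
  trace <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    remaining <- setdiff(candidates, selected)
    if (length(remaining) == 0) break
    ll0 <- log_lik_binom(current)
    entry <- purrr::map_dfr(remaining, function(term) {
      fit1 <- fit_glm_checked(model_formula(c(selected, term)), data)
      lr <- 2 * (log_lik_binom(fit1) - ll0)
      tibble::tibble(term = term, lr_statistic = lr,
                     p_value = stats::pchisq(lr, df = 1, lower.tail = FALSE))
    })
    entry <- entry[order(entry$p_value, entry$term), ]
    if (entry$p_value[1] >= entry_alpha) break
    selected <- c(selected, entry$term[1])
    current <- fit_glm_checked(model_formula(selected), data)
    trace[[length(trace) + 1]] <- tibble::tibble(
      step = step, action = "add", term = entry$term[1],
      lr_statistic = entry$lr_statistic[1], p_value = entry$p_value[1]
    )
    # backward check: remove any term whose LR p now exceeds removal_alpha
    repeat {
      if (length(selected) == 0) break
      ll_full <- log_lik_binom(current)
      removal <- purrr::map_dfr(selected, function(term) {
        fit0 <- fit_glm_checked(model_formula(setdiff(selected, term)), data)
        lr <- 2 * (ll_full - log_lik_binom(fit0))
        tibble::tibble(term = term, lr_statistic = lr,
                       p_value = stats::pchisq(lr, df = 1, lower.tail = FALSE))
      })
      removal <- removal[order(-removal$p_value, removal$term), ]
      if (removal$p_value[1] <= removal_alpha) break
      selected <- setdiff(selected, removal$term[1])
      current <- fit_glm_checked(model_formula(selected), data)
      trace[[length(trace) + 1]] <- tibble::tibble(
        step = step, action = "remove", term = removal$term[1],
        lr_statistic = removal$lr_statistic[1], p_value = removal$p_value[1]
      )
    }
  }
  cf <- stats::coef(current)
  se <- sqrt(diag(stats::vcov(current)))
  terms <- setdiff(names(cf), "(Intercept)")
  coeffs <- tibble::tibble(
    term = terms,
    estimate = unname(cf[terms]),
    std_error = unname(se[terms]),
    wald_chi_square = unname((cf[terms] / se[terms])^2),
    p_value = stats::pchisq(unname((cf[terms] / se[terms])^2), df = 1,
                            lower.tail = FALSE),
    odds_ratio = exp(unname(cf[terms])),
    or_ci_low = exp(unname(cf[terms] - 1.96 * se[terms])),
    or_ci_high = exp(unname(cf[terms] + 1.96 * se[terms])),
    odds_ratio_reversed = exp(-unname(cf[terms]))
  )
  structure(
    list(fit = current, selected = selected, coefficients = coeffs,
         trace = if (length(trace) > 0) dplyr::bind_rows(trace) else
           tibble::tibble(step = integer(), action = character(), term = character(),
                          lr_statistic = numeric(), p_value = numeric()),
         outcome = outcome, event_level = sprintf("%s == 1", outcome),
         entry_alpha = entry_alpha, removal_alpha = removal_alpha,
         n = nrow(data)),
    class = "forward_lr_fit"
  )
}

#' @export
print.forward_lr_fit <- function(x, ...) {
  cat("Forward-LR logistic regression (event:", x$event_level, ", n =", x$n, ")\n")
  if (length(x$selected) == 0) {
    cat("No variable met the entry criterion (alpha =", x$entry_alpha, ")\n")
  } else {
    print(x$coefficients)
  }
  invisible(x)
}

#' @export
tidy.forward_lr_fit <- function(x, ...) x$coefficients

#' @export
glance.forward_lr_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n, n_selected = length(x$selected),
    log_lik = as.numeric(stats::logLik(x$fit)),
    aic = stats::AIC(x$fit),
    entry_alpha = x$entry_alpha, removal_alpha = x$removal_alpha
  )
}
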