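default_continuous_marginals <- function() {
  # per-group mean/sd of each continuous feature, plus truncation bounds
  # imposed by the variable's physical domain (LP pressure additionally by
  # the 80-200 mmH2O inclusion window)
  tibble::tribble(
    ~var,                    ~mean_resp, ~sd_resp, ~mean_nonresp, ~sd_nonresp, ~lo,  ~hi,
    "age",                    71.59,      6.91,     70.71,         7.32,        1,    Inf,
    "lp_pressure",            129.40,     17.79,    134.20,        14.49,       80,   200,
    "disease_duration",       19.11,      7.44,     17.69,         8.12,        0.5,  Inf,
    "ei",                     0.36,       0.04,     0.35,          0.04,        0.01, 0.99,
    "ca",                     71.21,      14.62,    76.04,         15.06,       1,    179,
    "z_ei",                   0.46,       0.08,     0.47,          0.07,        0.01, 0.99,
    "bvr",                    0.76,       0.20,     0.81,          0.18,        0.01, Inf,
    "scca",                   46.25,      14.31,    50.24,         13.77,       1,    179,
    "temporal_horn_left",     8.12,       2.17,     7.65,          2.72,        0.1,  Inf,
    "temporal_horn_right",    7.80,       1.99,     7.33,          2.35,        0.1,  Inf,
    "third_ventricle_width",  11.50,      2.96,     10.94,         2.81,        0.1,  Inf,
    "posterior_horn_ratio",   0.62,       0.15,     0.60,          0.12,        0.01, 0.99
  )
}

default_binary_rates <- function() {
  tibble::tribble(
    ~var,                  ~rate_resp, ~rate_nonresp,
    "male",                 60 / 96,    50 / 70,
    "tap_positive",         61 / 96,    28 / 70,
    "desh",                 53 / 96,    8 / 70,
    "sym_gait",             93 / 96,    67 / 70,
    "sym_cognitive",        74 / 96,    55 / 70,
    "sym_urinary",          76 / 96,    54 / 70,
    "com_cardiovascular",   40 / 96,    33 / 70,
    "com_endocrine",        28 / 96,    16 / 70,
    "com_neurological",     33 / 96,    33 / 70
  )
}

#' Simulation configuration for a synthetic iNPH shunt cohort
#'
#' Defaults reproduce the published group-level marginals: 96 responders and
#' 70 non-responders; group-wise means/SDs for age, LP pressure, disease
#' duration (months) and all imaging features; group-wise rates for sex, tap
#' positivity, the DESH sign, the symptom triad and comorbidities. Feature
#' dependence is controlled by a latent Gaussian copula correlation matrix
#' (default: independence, since no correlation estimates are published).
#'
#' @param n_responders,n_non_responders Group sizes (defaults 96 and 70).
#' @param continuous Tibble of per-group continuous marginals; see
#'   `shuntpredict:::default_continuous_marginals()` for the format
#'   (`var`, `mean_resp`, `sd_resp`, `mean_nonresp`, `sd_nonresp`, `lo`,
#'   `hi`). Values are sampled from normals truncated to `[lo, hi]`.
#' @param binary Tibble of per-group positivity rates (`var`, `rate_resp`,
#'   `rate_nonresp`).
#' @param correlation Latent correlation matrix over
#'   `c(continuous$var, binary$var)` (symmetric positive definite with unit
#'   diagonal), or `NULL` for independence.
#' @param center_weights Named allocation probabilities over the recruiting
#'   centers (default three centers at 0.5/0.3/0.2, an uneven multicenter
#'   allocation).
#' @param ca_cutoff Callosal angle cut point used wherever dichotomization
#'   is required (degrees; default 68.7).
#' @return A `simulation_config` object (list).
#' @export
simulation_config <- function(n_responders = 96L, n_non_responders = 70L,
                              continuous = default_continuous_marginals(),
                              binary = default_binary_rates(),
                              correlation = NULL,
                              center_weights = c(C1 = 0.5, C2 = 0.3, C3 = 0.2),
                              ca_cutoff = 68.7) {
  if (n_responders <= 0 || n_non_responders <= 0) abort_domain("group sizes must be positive")
  if (any(binary$rate_resp < 0 | binary$rate_resp > 1) ||
      any(binary$rate_nonresp < 0 | binary$rate_nonresp > 1)) {
    abort_domain("binary rates must lie in [0, 1]")
  }
  if (any(continuous$sd_resp <= 0) || any(continuous$sd_nonresp <= 0)) {
    abort_domain("continuous SDs must be positive")
  }
  vars <- c(continuous$var, binary$var)
  if (!is.null(correlation)) {
    if (!is.matrix(correlation) || !isTRUE(all.equal(correlation, t(correlation))) ||
        !identical(sort(rownames(correlation)), sort(vars))) {
      abort_domain("`correlation` must be a symmetric matrix named over all latent variables")
    }
    correlation <- correlation[vars, vars]
    ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 1e-10) abort_domain("`correlation` must be positive definite")
  }
  structure(
    list(n_responders = as.integer(n_responders),
         n_non_responders = as.integer(n_non_responders),
         continuous = continuous, binary = binary, correlation = correlation,
         center_weights = center_weights / sum(center_weights),
         ca_cutoff = ca_cutoff),
    class = "simulation_config"
  )
}

# inverse-CDF transform of a latent standard normal to a truncated normal
truncnorm_from_z <- function(z, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  u <- stats::pnorm(z)
  stats::qnorm(plo + u * (phi - plo), mean, sd)
}

sample_group <- function(n, config, group, id_prefix) {
  cont <- config$continuous
  bin <- config$binary
  vars <- c(cont$var, bin$var)
  k <- length(vars)
  z <- matrix(stats::rnorm(n * k), nrow = n, ncol = k, dimnames = list(NULL, vars))
  if (!is.null(config$correlation)) {
    z <- z %*% chol(config$correlation)
    colnames(z) <- vars
  }
  resp <- group == "responder"
  out <- tibble::tibble(.rows = n)
  for (i in seq_len(nrow(cont))) {
    v <- cont$var[i]
    out[[v]] <- truncnorm_from_z(
      z[, v],
      mean = if (resp) cont$mean_resp[i] else cont$mean_nonresp[i],
      sd = if (resp) cont$sd_resp[i] else cont$sd_nonresp[i],
      lo = cont$lo[i], hi = cont$hi[i]
    )
  }
  for (i in seq_len(nrow(bin))) {
    v <- bin$var[i]
    rate <- if (resp) bin$rate_resp[i] else bin$rate_nonresp[i]
    # indicator increasing in z so latent correlation signs carry over to
    # observed associations; P(z > qnorm(1 - rate)) = rate
    out[[v]] <- z[, v] > stats::qnorm(1 - rate)
  }
  out$id <- sprintf("%s%04d", id_prefix, seq_len(n))
  out$center_id <- sample(names(config$center_weights), n, replace = TRUE,
                          prob = config$center_weights)
  out$sex <- ifelse(out$male, "male", "female")
  out$male <- NULL
  out$outcome <- if (resp) "responder" else "non_responder"
  out
}

# Draws a pre/post tap assessment consistent with a target tap status:
# positive subjects meet the gait criterion with margin; negative subjects
# miss all three criteria with margin (rounding to measurement precision
# cannot flip the classification).
backfill_tap_assessment <- function(tap_positive) {
  n <- length(tap_positive)
  pre_time <- round(stats::runif(n, 15, 40), 1)
  pre_steps <- as.integer(round(stats::runif(n, 20, 45)))
  pre_mmse <- as.integer(round(stats::runif(n, 18, 28)))
  pre_urinary <- as.integer(round(stats::runif(n, 2, 8)))
  impr_time <- ifelse(tap_positive, stats::runif(n, 0.22, 0.45),
                      stats::runif(n, -0.10, 0.15))
  impr_steps <- ifelse(tap_positive, stats::runif(n, 0.22, 0.45),
                       stats::runif(n, -0.10, 0.15))
  post_time <- round(pre_time * (1 - impr_time), 1)
  post_steps <- as.integer(round(pre_steps * (1 - impr_steps)))
  mmse_delta <- sample(c(-1L, 0L, 1L), n, replace = TRUE)
  post_mmse <- pmin(30L, pmax(0L, pre_mmse + mmse_delta))
  uri_delta <- sample(c(0L, 0L, 1L), n, replace = TRUE)  # never improves
  post_urinary <- pmin(10L, pre_urinary + uri_delta)
  tibble::tibble(
    pre_walk_time = pre_time, pre_walk_steps = pre_steps,
    pre_mmse = pre_mmse, pre_urinary = pre_urinary,
    post_walk_time = post_time, post_walk_steps = post_steps,
    post_mmse = post_mmse, post_urinary = post_urinary
  )
}

# Severity scores whose Krauss index lands on the intended side of 0.5.
backfill_severity <- function(responder) {
  n <- length(responder)
  pre <- as.integer(round(stats::runif(n, 4, 10)))
  drop <- ifelse(responder,
                 ceiling(pre * stats::runif(n, 0.5, 0.9)),
                 floor(pre * stats::runif(n, 0, 0.49)))
  tibble::tibble(preop_severity = pre,
                 postop_severity = pmax(0L, as.integer(pre - drop)))
}

#' Simulate a synthetic iNPH shunt cohort
#'
#' Per-group sampling through a latent Gaussian copula: continuous features
#' by truncated-normal inverse-CDF transform of the latent normals, binary
#' features by thresholding at the rate quantile. Tap assessments are
#' back-filled so that [classify_tap_response()] reproduces each subject's
#' sampled tap status, and severity scores so that [krauss_responder()]
#' reproduces group membership. Fully reproducible per seed.
#'
#' @param config A [simulation_config()] object.
#' @param seed Integer RNG seed.
#' @return A cohort tibble in [cohort_schema()] order.
#' @export
simulate_cohort <- function(config = simulation_config(), seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  grp <- dplyr::bind_rows(
    sample_group(config$n_responders, config, "responder", "R"),
    sample_group(config$n_non_responders, config, "non_responder", "N")
  )
  tap <- backfill_tap_assessment(grp$tap_positive)
  sev <- backfill_severity(grp$outcome == "responder")
  cohort <- dplyr::bind_cols(grp[setdiff(names(grp), "tap_positive")], tap, sev)
  cohort[, cohort_schema()$column]
}

#' Published group-level targets for reconstruction
#'
#' Loads the target file shipped with the package: exact integer counts of
#' tap-positive and DESH-positive subjects per outcome group, the 2-dp
#' sensitivity/specificity/AUC of the six prediction rules, and the reported
#' callosal angle cutoff.
#'
#' @param path Optional path to an alternative targets JSON file.
#' @return A list mirroring the JSON structure.
#' @export
table_targets <- function(path = NULL) {
  path <- path %||% system.file("extdata", "printed-targets.json",
                                package = "shuntpredict", mustWork = TRUE)
  jsonlite::read_json(path, simplifyVector = TRUE)
}

# cell order for a (tap, desh, ca) 2x2x2 table; 1 = positive
cell_names <- c("n111", "n110", "n101", "n100", "n011", "n010", "n001", "n000")

# Derived rule-positive counts from the 8 cells.
derived_counts <- function(cells) {
  with(as.list(cells), c(
    tap = n111 + n110 + n101 + n100,
    desh = n111 + n110 + n011 + n010,
    ca = n111 + n101 + n011 + n001,
    tap_desh = n111 + n110 + n101 + n100 + n011 + n010,
    tap_ca = n111 + n110 + n101 + n100 + n011 + n001,
    majority = n111 + n110 + n101 + n011
  ))
}

metric_from_count <- function(k, n, sens) if (sens) k / n else (n - k) / n

# Enumerate all cell solutions with the exact tap/DESH margins and the given
# rule-positive counts for ca / tap_desh / tap_ca / majority. Solutions are
# linear in one free parameter (the tap-/DESH+/CA+ cell), so enumeration is
# a single loop.
cells_for_counts <- function(n, tap_pos, desh_pos, ca_k, utd_k, utc_k, maj_k) {
  s <- tap_pos + desh_pos - utd_k   # n111 + n110
  q <- utc_k - tap_pos              # n011 + n001
  ce <- maj_k - s                   # n101 + n011
  diff_ae <- ca_k - q - maj_k + s   # n111 - n011
  out <- list()
  for (e in 0:max(0, min(desh_pos, n - tap_pos))) {  # e = n011
    a <- e + diff_ae
    c_ <- ce - e
    g <- q - e
    b <- s - a
    d <- tap_pos - s - c_
    f <- desh_pos - s - e
    h <- n - tap_pos - e - f - g
    cells <- c(n111 = a, n110 = b, n101 = c_, n100 = d,
               n011 = e, n010 = f, n001 = g, n000 = h)
    if (all(cells >= 0)) out[[length(out) + 1]] <- cells
  }
  out
}

solve_group <- function(n, tap_pos, desh_pos, targets, sens, tol = 0.005,
                        max_tuples = 50000) {
  # targets: named numeric (ca, tap_desh, tap_ca, majority), 2-dp values;
  # a NULL/NA entry leaves that rule unconstrained
  metric_names <- c("ca", "tap_desh", "tap_ca", "majority")
  constrained <- metric_names[vapply(metric_names, function(m) {
    !is.null(targets[[m]]) && !is.na(targets[[m]])
  }, logical(1))]
  dev_tab <- lapply(metric_names, function(m) {
    k <- 0:n
    dev <- if (m %in% constrained) {
      abs(metric_from_count(k, n, sens) - targets[[m]])
    } else {
      rep(0, n + 1)
    }
    ord <- order(dev, k)
    tibble::tibble(k = k[ord], dev = dev[ord])
  })
  names(dev_tab) <- metric_names
  thresholds <- sort(unique(unlist(lapply(dev_tab, function(t) t$dev))))
  for (thr in thresholds) {
    sets <- lapply(dev_tab, function(t) t$k[t$dev <= thr + 1e-12])
    if (prod(lengths(sets)) > max_tuples) {
      # keep only counts nearest the target; enough to find min-max-dev
      sets <- lapply(dev_tab, function(t) utils::head(t$k[t$dev <= thr + 1e-12], 25))
    }
    tuples <- expand.grid(ca = sets$ca, tap_desh = sets$tap_desh,
                          tap_ca = sets$tap_ca, majority = sets$majority)
    sols <- list()
    for (i in seq_len(nrow(tuples))) {
      found <- cells_for_counts(n, tap_pos, desh_pos, tuples$ca[i],
                                tuples$tap_desh[i], tuples$tap_ca[i],
                                tuples$majority[i])
      sols <- c(sols, found)
    }
    if (length(sols) > 0) {
      cells_df <- tibble::as_tibble(do.call(rbind, sols))
      cells_df <- dplyr::distinct(cells_df)
      cells_df <- dplyr::arrange(cells_df, dplyr::across(dplyr::all_of(cell_names)))
      devs <- apply(cells_df, 1, function(row) {
        dc <- derived_counts(row)
        if (length(constrained) == 0) return(0)
        max(abs(metric_from_count(dc[constrained], n, sens) -
                  unlist(targets[constrained])))
      })
      # keep only the minimal max-deviation set at this threshold
      keep <- devs <= min(devs) + 1e-12
      cells_df <- cells_df[keep, ]
      devs <- devs[keep]
      return(list(solutions = cells_df, max_abs_deviation = min(devs),
                  exact = min(devs) < tol, n = n, tap_pos = tap_pos,
                  desh_pos = desh_pos, sens = sens, targets = targets))
    }
  }
  list(solutions = tibble::as_tibble(stats::setNames(
    as.list(rep(NA_integer_, 8)), cell_names))[0, ],
    max_abs_deviation = Inf, exact = FALSE, n = n, tap_pos = tap_pos,
    desh_pos = desh_pos, sens = sens, targets = targets)
}

#' Reconstruct joint 2x2x2 contingency structure from printed group counts
#'
#' The published report gives, per outcome group, only the margins of the
#' tap test and DESH sign (exact integer counts) and 2-dp accuracy values
#' for the callosal angle and the three combination rules. This solver
#' enumerates all integer 2x2x2 tables over (tap, DESH, CA-positive) per
#' group that honor the exact margins and match every 2-dp target within
#' the stated tolerance; when no exact table exists it returns the tables
#' minimizing the maximum absolute deviation, in deterministic
#' (lexicographic) order, and flags the group as inexact. Contradictory
#' integer targets yield an infeasibility report, not an error.
#'
#' @param targets Target list from [table_targets()].
#' @param tol Match tolerance around each 2-dp value (default 0.005,
#'   agnostic to the rounding convention used in the source report).
#' @return A `joint_reconstruction` object: list with elements `responders`
#'   and `non_responders` (each holding `solutions`, `exact`,
#'   `max_abs_deviation`, margins and targets), `derived` (tibble of rule
#'   metrics recomputed from the canonical solution pair) and `notes`
#'   (character vector surfacing arithmetic inconsistencies in the source
#'   values).
#' @export
reconstruct_joint_tables <- function(targets = table_targets(), tol = 0.005) {
  t4 <- targets$table4
  infeasible <- function(group) {
    n <- targets$group_sizes[[group]]
    targets$tap_positive[[group]] > n || targets$desh_positive[[group]] > n ||
      targets$tap_positive[[group]] < 0 || targets$desh_positive[[group]] < 0
  }
  run_group <- function(group, sens) {
    if (infeasible(group)) {
      return(list(solutions = tibble::tibble(), max_abs_deviation = Inf,
                  exact = FALSE, n = targets$group_sizes[[group]],
                  tap_pos = targets$tap_positive[[group]],
                  desh_pos = targets$desh_positive[[group]], sens = sens,
                  targets = NULL, infeasible = TRUE))
    }
    key <- if (sens) "sensitivity" else "specificity"
    tg <- list(ca = t4$ca[[key]], tap_desh = t4$tap_desh[[key]],
               tap_ca = t4$tap_ca[[key]], majority = t4$majority[[key]])
    out <- solve_group(targets$group_sizes[[group]],
                       targets$tap_positive[[group]],
                       targets$desh_positive[[group]], tg, sens, tol)
    out$infeasible <- nrow(out$solutions) == 0
    out
  }
  resp <- run_group("responders", sens = TRUE)
  nonresp <- run_group("non_responders", sens = FALSE)
  notes <- character(0)
  # surface the narrative-vs-table inconsistency in the source counts
  extra_desh <- round(t4$tap_desh$sensitivity * targets$group_sizes$responders) -
    targets$tap_positive$responders
  extra_ca <- round(t4$tap_ca$sensitivity * targets$group_sizes$responders) -
    targets$tap_positive$responders
  notes <- c(notes, sprintf(
    paste("The narrative counts of additional responders captured by the OR",
          "combinations (10 for tap+DESH, 16 for tap+CA) are arithmetically",
          "inconsistent with the tabulated sensitivities, which imply %d and %d",
          "additional responders; the reconstruction trusts the tabulated values."),
    extra_desh, extra_ca))
  for (g in list(list(name = "responder", r = resp),
                 list(name = "non-responder", r = nonresp))) {
    notes <- c(notes, if (g$r$exact) {
      sprintf("%s group: %d exact integer table(s) reproduce every 2-dp target within %.3f.",
              g$name, nrow(g$r$solutions), tol)
    } else if (nrow(g$r$solutions) > 0) {
      sprintf(paste("%s group: no integer table matches all 2-dp targets within %.3f;",
                    "%d minimal-deviation table(s) returned (max abs deviation %.4f)."),
              g$name, tol, nrow(g$r$solutions), g$r$max_abs_deviation)
    } else {
      sprintf("%s group: targets are contradictory; no feasible table exists.", g$name)
    })
  }
  res <- structure(
    list(responders = resp, non_responders = nonresp, tol = tol,
         targets = targets, notes = notes),
    class = "joint_reconstruction"
  )
  res$derived <- derived_metrics(res)
  res
}

# Rule metrics recomputed from the canonical (first) solution of each group.
derived_metrics <- function(recon) {
  if (nrow(recon$responders$solutions) == 0 ||
      nrow(recon$non_responders$solutions) == 0) {
    return(tibble::tibble())
  }
  rc <- derived_counts(unlist(recon$responders$solutions[1, ]))
  nc <- derived_counts(unlist(recon$non_responders$solutions[1, ]))
  nr <- recon$responders$n
  nn <- recon$non_responders$n
  tibble::tibble(
    rule = names(rc),
    sensitivity = unname(rc) / nr,
    specificity = (nn - unname(nc)) / nn,
    auc = binary_auc(unname(rc) / nr, (nn - unname(nc)) / nn)
  )
}

#' @export
print.joint_reconstruction <- function(x, ...) {
  cat("Joint 2x2x2 reconstruction (tolerance ", x$tol, ")\n", sep = "")
  for (note in x$notes) cat("- ", note, "\n", sep = "")
  invisible(x)
}

#' @export
tidy.joint_reconstruction <- function(x, ...) x$derived

#' @export
glance.joint_reconstruction <- function(x, ...) {
  tibble::tibble(
    responder_exact = x$responders$exact,
    responder_solutions = nrow(x$responders$solutions),
    responder_max_dev = x$responders$max_abs_deviation,
    non_responder_exact = x$non_responders$exact,
    non_responder_solutions = nrow(x$non_responders$solutions),
    non_responder_max_dev = x$non_responders$max_abs_deviation
  )
}

truncnorm_sample <- function(n, mean, sd, lo, hi) {
  truncnorm_from_z(stats::rnorm(n), mean, sd, lo, hi)
}

#' Build a fixture cohort from a reconstructed joint table
#'
#' Emits one patient record per cell occupant of the canonical solution of
#' each outcome group, with tap/DESH/CA-positivity exactly as the cell
#' dictates: the callosal angle is drawn from the group's truncated normal
#' restricted to the correct side of the cutoff, tap assessments are
#' back-filled to reproduce the cell's tap status and severity scores to
#' reproduce group membership. Running the full pipeline on the fixture
#' with the cutoff pinned therefore reproduces the solution's derived
#' metrics exactly.
#'
#' @param recon A `joint_reconstruction` from [reconstruct_joint_tables()].
#' @param config A [simulation_config()] supplying the continuous marginals.
#' @param seed Integer RNG seed.
#' @return A cohort tibble in [cohort_schema()] order.
#' @export
build_fixture_cohort <- function(recon, config = simulation_config(), seed = 1L) {
  stopifnot(inherits(recon, "joint_reconstruction"))
  if (nrow(recon$responders$solutions) == 0 ||
      nrow(recon$non_responders$solutions) == 0) {
    abort_domain("reconstruction holds no feasible solution to build a fixture from")
  }
  set.seed(seed)
  cutoff <- recon$targets$ca_cutoff %||% config$ca_cutoff
  eps <- 0.01
  cont <- config$continuous
  build_group <- function(sol_row, n, group, id_prefix) {
    cells <- unlist(sol_row)
    flags <- expand.grid(ca_pos = c(TRUE, FALSE), desh = c(TRUE, FALSE),
                         tap = c(TRUE, FALSE))[, c("tap", "desh", "ca_pos")]
    # cell_names order: n111 n110 n101 n100 n011 n010 n001 n000
    flags <- flags[order(-flags$tap, -flags$desh, -flags$ca_pos), ]
    per <- flags[rep(seq_len(8), cells), ]
    resp <- group == "responder"
    m <- function(v, col_m, col_s) {
      i <- match(v, cont$var)
      list(mean = if (resp) cont$mean_resp[i] else cont$mean_nonresp[i],
           sd = if (resp) cont$sd_resp[i] else cont$sd_nonresp[i],
           lo = cont$lo[i], hi = cont$hi[i])
    }
    draw <- function(v) {
      p <- m(v)
      truncnorm_sample(n, p$mean, p$sd, p$lo, p$hi)
    }
    ca_p <- m("ca")
    ca <- ifelse(per$ca_pos,
                 truncnorm_sample(n, ca_p$mean, ca_p$sd, ca_p$lo, cutoff - eps),
                 truncnorm_sample(n, ca_p$mean, ca_p$sd, cutoff + eps, ca_p$hi))
    bin_rate <- function(v) {
      i <- match(v, config$binary$var)
      if (resp) config$binary$rate_resp[i] else config$binary$rate_nonresp[i]
    }
    out <- tibble::tibble(
      id = sprintf("%s%04d", id_prefix, seq_len(n)),
      center_id = sample(names(config$center_weights), n, replace = TRUE,
                         prob = config$center_weights),
      age = draw("age"),
      sex = ifelse(stats::runif(n) <= bin_rate("male"), "male", "female"),
      lp_pressure = draw("lp_pressure"),
      disease_duration = draw("disease_duration"),
      sym_gait = stats::runif(n) <= bin_rate("sym_gait"),
      sym_cognitive = stats::runif(n) <= bin_rate("sym_cognitive"),
      sym_urinary = stats::runif(n) <= bin_rate("sym_urinary"),
      com_cardiovascular = stats::runif(n) <= bin_rate("com_cardiovascular"),
      com_endocrine = stats::runif(n) <= bin_rate("com_endocrine"),
      com_neurological = stats::runif(n) <= bin_rate("com_neurological"),
      ei = draw("ei"),
      desh = per$desh,
      ca = ca,
      z_ei = draw("z_ei"),
      bvr = draw("bvr"),
      scca = draw("scca"),
      temporal_horn_left = draw("temporal_horn_left"),
      temporal_horn_right = draw("temporal_horn_right"),
      third_ventricle_width = draw("third_ventricle_width"),
      posterior_horn_ratio = draw("posterior_horn_ratio"),
      outcome = if (resp) "responder" else "non_responder"
    )
    dplyr::bind_cols(out, backfill_tap_assessment(per$tap),
                     backfill_severity(rep(resp, n)))
  }
  cohort <- dplyr::bind_rows(
    build_group(recon$responders$solutions[1, ], recon$responders$n,
                "responder", "R"),
    build_group(recon$non_responders$solutions[1, ], recon$non_responders$n,
                "non_responder", "N")
  )
  cohort[, cohort_schema()$column]
}
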