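#' Cross-tabulate binary predictions against responder status
#'
#' Subjects with a missing prediction or missing truth are excluded and
#' counted in the `n_excluded` tally rather than silently dropped.
#'
#' @param predicted Logical vector of test results (positive = predicts
#'   response).
#' @param truth Logical vector of true responder status, same length.
#' @return A `confusion_counts` object: list with integer fields `tp`, `fp`,
#'   `fn`, `tn` and `n_excluded`.
#' @export
confusion_counts <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    abort_domain("`predicted` and `truth` must have the same length")
  }
  keep <- !is.na(predicted) & !is.na(truth)
  p <- predicted[keep]
  t <- truth[keep]
  structure(
    list(tp = sum(p & t), fp = sum(p & !t), fn = sum(!p & t), tn = sum(!p & !t),
         n_excluded = sum(!keep)),
    class = "confusion_counts"
  )
}

#' Build a confusion_counts object from its four cells
#'
#' @param tp,fp,fn,tn Nonnegative integer cell counts.
#' @return A `confusion_counts` object.
#' @export
as_confusion_counts <- function(tp, fp, fn, tn) {
  cells <- c(tp, fp, fn, tn)
  if (any(cells < 0) || any(cells != round(cells))) {
    abort_domain("confusion cells must be nonnegative integers")
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 tn = as.integer(tn), n_excluded = 0L),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("confusion counts: TP", x$tp, " FP", x$fp, " FN", x$fn, " TN", x$tn,
      " (excluded:", x$n_excluded, ")\n")
  invisible(x)
}

#' Trapezoidal AUC of a single-operating-point (binary) test
#'
#' The ROC curve of a dichotomous test has three points, (0,0),
#' (1 - specificity, sensitivity) and (1,1); its trapezoidal area is exactly
#' `(sensitivity + specificity) / 2`.
#'
#' @param sensitivity,specificity Fractions in `[0, 1]`.
#' @return The area, in `[0, 1]`. Vectorized and symmetric in its arguments.
#' @examples
#' binary_auc(0.64, 0.60) # 0.62
#' @export
binary_auc <- function(sensitivity, specificity) {
  check_prob(sensitivity, "sensitivity")
  check_prob(specificity, "specificity")
  (sensitivity + specificity) / 2
}

#' Diagnostic performance from confusion counts
#'
#' Sensitivity, specificity, predictive values and the binary-test AUC,
#' returned raw and rounded to the 2-decimal report convention
#' (half away from zero).
#'
#' @param counts A `confusion_counts` object (or anything accepted by
#'   [as_confusion_counts()] when given as a length-4 numeric `c(tp, fp,
#'   fn, tn)`).
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`, `auc` plus `sensitivity_2dp`,
#'   `specificity_2dp`, `auc_2dp`. An empty predicted-positive margin makes
#'   PPV undefined (`NA` with no error); empty truth classes are an error
#'   naming the class.
#' @export
diagnostic_performance <- function(counts) {
  if (is.numeric(counts) && length(counts) == 4) {
    counts <- as_confusion_counts(counts[1], counts[2], counts[3], counts[4])
  }
  stopifnot(inherits(counts, "confusion_counts"))
  if (counts$tp + counts$fn == 0) abort_domain("no positive (responder) subjects in truth")
  if (counts$tn + counts$fp == 0) abort_domain("no negative (non-responder) subjects in truth")
  sens <- counts$tp / (counts$tp + counts$fn)
  spec <- counts$tn / (counts$tn + counts$fp)
  ppv <- if (counts$tp + counts$fp == 0) NA_real_ else counts$tp / (counts$tp + counts$fp)
  npv <- if (counts$tn + counts$fn == 0) NA_real_ else counts$tn / (counts$tn + counts$fn)
  auc <- binary_auc(sens, spec)
  tibble::tibble(
    tp = counts$tp, fp = counts$fp, fn = counts$fn, tn = counts$tn,
    sensitivity = sens, specificity = spec, ppv = ppv, npv = npv, auc = auc,
    sensitivity_2dp = round_half_away(sens), specificity_2dp = round_half_away(spec),
    auc_2dp = round_half_away(auc)
  )
}

#' ROC curve and Youden-index optimal cutoff for a continuous marker
#'
#' Operating points are taken at midpoints between adjacent distinct marker
#' values, with -Inf/+Inf sentinels so (0,0) and (1,1) are always on the
#' curve. The AUC is the trapezoidal area, which with this construction
#' equals the Mann-Whitney U statistic over n1*n2 with half credit for
#' ties. The optimal cutoff maximizes Youden's J = sensitivity +
#' specificity - 1; when several thresholds tie on J, the one with higher
#' specificity is returned (and among those, the most extreme threshold),
#' making the choice deterministic. A constant marker yields AUC 0.5 and an
#' undefined cutoff, flagged rather than raised.
#'
#' @param marker Numeric marker values.
#' @param truth Logical responder status, same length.
#' @param direction `"lower_is_positive"` (e.g. callosal angle: smaller
#'   angles predict response, test positive when marker <= threshold) or
#'   `"higher_is_positive"`.
#' @return A `shunt_roc` object: list with `points` (tibble of threshold,
#'   sensitivity, specificity, fpr, youden_j), `auc`, `youden_j_max`,
#'   `optimal_cutoff`, `cutoff_undefined`, `direction`, `n_pos`, `n_neg`.
#' @export
roc_youden <- function(marker, truth, direction = c("lower_is_positive",
                                                    "higher_is_positive")) {
  direction <- match.arg(direction)
  if (length(marker) != length(truth)) abort_domain("marker and truth lengths differ")
  keep <- !is.na(marker) & !is.na(truth)
  marker <- marker[keep]
  truth <- as.logical(truth[keep])
  n_pos <- sum(truth)
  n_neg <- sum(!truth)
  if (n_pos < 2 || n_neg < 2) abort_domain("need at least 2 subjects per truth class")
  v <- sort(unique(marker))
  mids <- if (length(v) > 1) (v[-1] + v[-length(v)]) / 2 else numeric(0)
  # cumulative class counts at each distinct value (ascending)
  pos_by_v <- cumsum(vapply(split(truth, factor(marker, levels = v)), sum,
                            numeric(1)))
  all_by_v <- cumsum(tabulate(match(marker, v), nbins = length(v)))
  neg_by_v <- all_by_v - pos_by_v
  if (direction == "lower_is_positive") {
    # at a midpoint after v[i], positives are the subjects with marker <= v[i]
    sens <- c(0, pos_by_v[-length(v)], n_pos) / n_pos
    spec <- c(n_neg, n_neg - neg_by_v[-length(v)], 0) / n_neg
    thresholds <- c(-Inf, mids, Inf)
  } else {
    sens <- c(0, n_pos - pos_by_v[-length(v)], n_pos) / n_pos
    spec <- c(n_neg, neg_by_v[-length(v)], 0) / n_neg
    thresholds <- c(Inf, mids, -Inf)
  }
  pts <- tibble::tibble(threshold = thresholds, sensitivity = sens,
                        specificity = spec)
  pts$fpr <- 1 - pts$specificity
  pts$youden_j <- pts$sensitivity + pts$specificity - 1
  # trapezoid over the curve ordered by false-positive rate
  ord <- order(pts$fpr, pts$sensitivity)
  x <- pts$fpr[ord]
  y <- pts$sensitivity[ord]
  auc <- sum(diff(x) * (y[-1] + y[-length(y)]) / 2)
  j_max <- max(pts$youden_j)
  cutoff_undefined <- length(v) == 1 || j_max <= 0
  if (cutoff_undefined) {
    cutoff <- NA_real_
  } else {
    cand <- pts[abs(pts$youden_j - j_max) < 1e-12, ]
    cand <- cand[order(-cand$specificity,
                       if (direction == "lower_is_positive") cand$threshold
                       else -cand$threshold), ]
    cutoff <- cand$threshold[1]
  }
  structure(
    list(points = pts, auc = auc, youden_j_max = j_max, optimal_cutoff = cutoff,
         cutoff_undefined = cutoff_undefined, direction = direction,
         n_pos = n_pos, n_neg = n_neg, n_excluded = sum(!keep)),
    class = "shunt_roc"
  )
}

#' @export
print.shunt_roc <- function(x, ...) {
  cat("ROC (", x$direction, "): AUC ", format(x$auc, digits = 4),
      ", max Youden J ", format(x$youden_j_max, digits = 4),
      ", optimal cutoff ",
      if (x$cutoff_undefined) "undefined" else format(x$optimal_cutoff, digits = 4),
      " [", x$n_pos, " pos / ", x$n_neg, " neg]\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @export
tidy.shunt_roc <- function(x, ...) x$points

#' @export
glance.shunt_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, youden_j_max = x$youden_j_max,
                 optimal_cutoff = x$optimal_cutoff,
                 cutoff_undefined = x$cutoff_undefined,
                 n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Plot a ROC curve with its Youden-optimal operating point
#'
#' @param object A `shunt_roc` object from [roc_youden()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.shunt_roc <- function(object, ...) {
  pts <- object$points[order(object$points$fpr, object$points$sensitivity), ]
  opt <- object$points[which.max(object$points$youden_j), ]
  ggplot2::ggplot(pts, ggplot2::aes(x = .data$fpr, y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_point(data = opt, colour = "red", size = 2) +
    ggplot2::labs(
      x = "1 - specificity", y = "Sensitivity",
      title = sprintf("ROC curve (AUC = %.3f)", object$auc),
      subtitle = if (object$cutoff_undefined) "Youden cutoff undefined"
      else sprintf("Youden-optimal cutoff = %.2f (J = %.3f)",
                   object$optimal_cutoff, object$youden_j_max)
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
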