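#' Evans index
#'
#' Ratio of the maximum width of the frontal horns of the lateral ventricles
#' to the maximal internal diameter of the skull measured at the same axial
#' level. Values above 0.3 define radiological ventricular enlargement.
#'
#' @param frontal_horn_width Frontal horn width in mm (> 0).
#' @param skull_inner_diameter Maximal internal skull diameter in mm
#'   (> `frontal_horn_width`).
#' @return The ratio, in (0, 1). Vectorized.
#' @examples
#' evans_index(36, 100) # 0.36
#' @export
evans_index <- function(frontal_horn_width, skull_inner_diameter) {
  if (any(frontal_horn_width <= 0) || any(skull_inner_diameter <= 0)) {
    abort_domain("widths and diameters must be positive")
  }
  if (any(frontal_horn_width >= skull_inner_diameter)) {
    abort_domain("frontal horn width must be smaller than the skull diameter")
  }
  frontal_horn_width / skull_inner_diameter
}

#' z-Evans index
#'
#' Maximum z-axial (vertical) length of the frontal horns of the lateral
#' ventricle (A) over the maximum cranial z-axial length at the midline (B),
#' both taken on the coronal plane at the anterior commissure.
#'
#' @param a Ventricular z-axial length A in mm, 0 < A < B.
#' @param b Cranial z-axial length B in mm.
#' @return A/B. Vectorized.
#' @examples
#' z_evans_index(46, 100) # 0.46
#' @export
z_evans_index <- function(a, b) {
  if (any(a <= 0) || any(b <= 0)) abort_domain("lengths must be positive")
  if (any(a >= b)) abort_domain("ventricular length A must be smaller than cranial length B")
  a / b
}

#' Brain-per-ventricle ratio
#'
#' The maximum z-axial length of the brain just above the lateral ventricle
#' (B - A) divided by the maximum z-axial length of the lateral ventricle
#' (A), using the same coronal landmarks as [z_evans_index()]. Identically
#' equal to B/A - 1.
#'
#' @inheritParams z_evans_index
#' @return (B - A)/A. Vectorized.
#' @examples
#' brain_per_ventricle_ratio(10, 17.6) # 0.76
#' @export
brain_per_ventricle_ratio <- function(a, b) {
  if (any(a <= 0)) abort_domain("ventricular length A must be positive")
  if (any(b <= a)) abort_domain("cranial length B must exceed ventricular length A")
  (b - a) / a
}

#' Posterior horn ratio of the lateral ventricle
#'
#' Ratio of the maximum width of the posterior horns of the lateral
#' ventricles to the maximal internal skull diameter at the same axial
#' level.
#'
#' @param posterior_horn_width Posterior horn width in mm (> 0).
#' @param skull_inner_diameter Internal skull diameter at the same level, mm.
#' @return The ratio. Vectorized.
#' @examples
#' posterior_horn_ratio(62, 100) # 0.62
#' @export
posterior_horn_ratio <- function(posterior_horn_width, skull_inner_diameter) {
  if (any(posterior_horn_width <= 0) || any(skull_inner_diameter <= 0)) {
    abort_domain("widths and diameters must be positive")
  }
  if (any(posterior_horn_width >= skull_inner_diameter)) {
    abort_domain("posterior horn width must be smaller than the skull diameter")
  }
  posterior_horn_width / skull_inner_diameter
}

#' Compute imaging indices for a table of landmark measurements
#'
#' Batch interface over the scalar index functions: takes a data frame of
#' raw landmark measurements (one row per scan) and appends the derived
#' indices. Angles (callosal angle, splenium angle), the DESH sign, horn
#' widths and third-ventricle width are direct measurements with no
#' computable formula and pass through validation only.
#'
#' @param landmarks Data frame with columns `frontal_horn_width`,
#'   `skull_inner_diameter`, `z_frontal_horn_length`, `z_cranial_length`,
#'   `posterior_horn_width`, `skull_inner_diameter_at_posterior` (all mm).
#' @return The input tibble with columns `ei`, `z_ei`, `bvr`,
#'   `posterior_horn_ratio` appended.
#' @export
compute_imaging_indices <- function(landmarks) {
  need <- c("frontal_horn_width", "skull_inner_diameter", "z_frontal_horn_length",
            "z_cranial_length", "posterior_horn_width",
            "skull_inner_diameter_at_posterior")
  missing <- setdiff(need, names(landmarks))
  if (length(missing) > 0) {
    abort_domain(sprintf("landmark table is missing column(s): %s",
                         paste(missing, collapse = ", ")))
  }
  dplyr::mutate(
    tibble::as_tibble(landmarks),
    ei = evans_index(.data$frontal_horn_width, .data$skull_inner_diameter),
    z_ei = z_evans_index(.data$z_frontal_horn_length, .data$z_cranial_length),
    bvr = brain_per_ventricle_ratio(.data$z_frontal_horn_length, .data$z_cranial_length),
    posterior_horn_ratio = posterior_horn_ratio(
      .data$posterior_horn_width, .data$skull_inner_diameter_at_posterior
    )
  )
}
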