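#' Round half away from zero
#'
#' Base [round()] uses banker's rounding (half to even), which cannot
#' reproduce printed report values such as 0.595 -> 0.60. Report tables use
#' half-away-from-zero at a fixed number of decimals instead.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 2, the report convention).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_away(0.595) # 0.60, not 0.59
#' @export
round_half_away <- function(x, digits = 2) {
  m <- 10^digits
  # add a one-ulp nudge so values stored as e.g. 0.59499999... from decimal
  # literals like 0.595 still round up
  sign(x) * floor(abs(x) * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used only for provenance stamps in reports (stable across platforms).
fnv1a_hash <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  bytes <- utf8ToInt(x)
  # xor in 16-bit halves: doubles hold the 32-bit state exactly, but
  # bitwXor() only accepts values below 2^31
  xor32 <- function(a, b) {
    bitwXor(as.integer(a %/% 65536), as.integer(b %/% 65536)) * 65536 +
      bitwXor(as.integer(a %% 65536), as.integer(b %% 65536))
  }
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    # 32-bit modular multiply by the FNV prime, split so every intermediate
    # product stays below 2^53 and doubles remain exact
    lo <- h %% 65536
    hi <- h %/% 65536
    h <- (lo * 16777619 + ((hi * 16777619) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_domain <- function(msg) stop(msg, call. = FALSE)

check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    abort_domain(sprintf("`%s` must lie in [0, 1]", name))
  }
  invisible(x)
}
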