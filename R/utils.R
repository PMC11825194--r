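# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Plain half-up rounding (2.5 -> 3, 3.125 -> 3.13 at 2 digits), unlike
#' [base::round()] which rounds half to even.  Used wherever a reported
#' quantity is defined at a fixed number of decimals.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Per-patient RNG stream seed derived from (cohort seed, patient index) so a
# cohort can be extended without disturbing existing patients.  Kept below
# 2^31 (R integers are 32-bit); arithmetic stays exact in doubles (< 2^53).
derive_patient_seed <- function(seed, i) {
  s <- as.numeric(seed) %% 2147483647
  as.integer((s * 48271 + as.numeric(i) * 104729) %% 2147483629 + 1)
}

# Strict ISO-8601 date parsing; returns NA for anything that does not
# round-trip through format().
parse_iso_date <- function(x) {
  x <- as.character(x)
  d <- as.Date(x, format = "%Y-%m-%d", optional = TRUE)
  bad <- !is.na(d) & format(d, "%Y-%m-%d") != x
  d[bad] <- as.Date(NA)
  d
}

weeks_to_days <- function(weeks) as.integer(round(weeks * 7))

# last-observation-carried-forward with leading NAs filled from the first
# non-missing value; errors (caller supplies context) if all missing
locf_fill <- function(x) {
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  idx <- cumsum(ok)
  filled <- x[ok][pmax(idx, 1L)]
  filled
}

`%||%` <- function(a, b) if (is.null(a)) b else a
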