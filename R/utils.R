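# Shared display/numeric helpers.

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (the convention of most
#' spreadsheet and social-science software), unlike base `round()`'s
#' round-half-even. Used only for display-layer parity; analysis values are
#' kept at full precision.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a p-value for display
#'
#' Three decimals with a `"<0.001"` floor, matching the customary table
#' style.
#'
#' @param p numeric p-value(s).
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.001, "<0.001", sprintf("%.3f", p)))
}

#' Bonferroni-adjusted significance threshold
#'
#' Returns `alpha / m_tests`. The display layer rounds it to four
#' decimals (e.g. 0.05 / 37 displays as 0.0014).
#'
#' @param alpha family-wise error rate in (0, 1].
#' @param m_tests positive integer number of tests.
#' @return The adjusted threshold (full precision).
#' @export
bonferroni_threshold <- function(alpha = 0.05, m_tests = 1L) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must be a single value in (0, 1]")
  if (!is.numeric(m_tests) || length(m_tests) != 1L || m_tests < 1 ||
      m_tests != floor(m_tests))
    stop("m_tests must be a positive integer")
  alpha / m_tests
}
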