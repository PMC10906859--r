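# Dual-factor classification: cross well-being band with SDQ caseness.

.status_levels <- c("complete", "symptomatic_but_content", "vulnerable", "troubled")
.status_abbrev <- c(complete = "C", symptomatic_but_content = "S",
                    vulnerable = "V", troubled = "T")

#' Classify respondents into the four dual-factor status groups
#'
#' Crosses the collapsed MHC-SF well-being band with SDQ caseness:
#' flourishing without problems is *complete* mental health (C);
#' flourishing with problems is *symptomatic but content* (S); moderate-to-
#' low well-being without problems is *vulnerable* (V); moderate-to-low
#' well-being with problems is *troubled* (T). Vectorised; a respondent
#' missing either input is left unclassified (`NA`), never dropped.
#'
#' @param mhc_collapsed character vector with values `"flourishing"` or
#'   `"moderate_to_low"` (or `NA`).
#' @param sdq_caseness logical vector (or `NA`), `TRUE` = mental health
#'   problems.
#' @return Factor with levels `complete`, `symptomatic_but_content`,
#'   `vulnerable`, `troubled`.
#' @examples
#' classify_status("flourishing", FALSE)      # complete
#' classify_status("moderate_to_low", TRUE)   # troubled
#' @export
classify_status <- function(mhc_collapsed, sdq_caseness) {
  mhc_collapsed <- as.character(mhc_collapsed)
  bad <- mhc_collapsed[!is.na(mhc_collapsed) &
                         !mhc_collapsed %in% c("flourishing", "moderate_to_low")]
  if (length(bad))
    stop("unknown well-being band: ", bad[1L])
  if (length(mhc_collapsed) != length(sdq_caseness))
    stop("mhc_collapsed and sdq_caseness must have equal length")
  sdq_caseness <- as.logical(sdq_caseness)
  out <- ifelse(is.na(mhc_collapsed) | is.na(sdq_caseness), NA_character_,
    ifelse(mhc_collapsed == "flourishing",
           ifelse(sdq_caseness, "symptomatic_but_content", "complete"),
           ifelse(sdq_caseness, "troubled", "vulnerable")))
  factor(out, levels = .status_levels)
}

#' Tabulate the dual-factor status distribution
#'
#' Counts respondents per status group and converts to percentages of
#' classified respondents, rounded half-up to one decimal for display
#' parity with published tables (full-precision proportions are kept).
#' Unclassified (`NA`) respondents are reported in `n_unclassified`.
#'
#' @param statuses factor from [classify_status()].
#' @return List of class `status_distribution` with `counts`,
#'   `proportions` (rounded percentages), `proportions_exact`,
#'   `n_classified`, `n_unclassified`, and `independence_test` (a
#'   chi-squared test of independence on the underlying 2x2 well-being by
#'   caseness table, offered as an interpretation of the customary
#'   cross-table p-value).
#' @examples
#' s <- classify_status(c("flourishing", "moderate_to_low"), c(FALSE, TRUE))
#' tabulate_status(s)
#' @export
tabulate_status <- function(statuses) {
  if (length(statuses) == 0L) stop("no statuses to tabulate")
  statuses <- factor(statuses, levels = .status_levels)
  counts <- table(statuses)
  n_classified <- sum(counts)
  if (n_classified == 0L) stop("all statuses are unclassified")
  prop <- 100 * as.numeric(counts) / n_classified
  names(prop) <- names(counts)

  # 2x2 well-being band x caseness table implied by the four cells
  m <- matrix(c(counts["complete"], counts["symptomatic_but_content"],
                counts["vulnerable"], counts["troubled"]),
              nrow = 2, byrow = TRUE,
              dimnames = list(wellbeing = c("flourishing", "moderate_to_low"),
                              problems = c("no", "yes")))
  indep <- if (all(rowSums(m) > 0) && all(colSums(m) > 0))
    suppressWarnings(stats::chisq.test(m, correct = FALSE)) else NULL

  structure(list(
    counts = stats::setNames(as.integer(counts), names(counts)),
    proportions = round_half_up(prop, 1),
    proportions_exact = prop,
    n_classified = as.integer(n_classified),
    n_unclassified = sum(is.na(statuses)),
    independence_test = indep), class = "status_distribution")
}

#' @export
print.status_distribution <- function(x, ...) {
  cat("Dual-factor mental health status (n classified =", x$n_classified)
  if (x$n_unclassified > 0) cat("; unclassified =", x$n_unclassified)
  cat(")\n")
  for (s in names(x$counts))
    cat(sprintf("  %-24s (%s)  n = %4d  (%.1f%%)\n", s, .status_abbrev[[s]],
                x$counts[[s]], x$proportions[[s]]))
  if (!is.null(x$independence_test))
    cat(sprintf("  well-being x problems independence: X2 = %.2f, p = %s\n",
                unname(x$independence_test$statistic),
                format_pvalue(x$independence_test$p.value)))
  invisible(x)
}
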