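# Instrument scoring: MHC-SF, SDQ, CYRM-12, and internal consistency.

#' Score the Mental Health Continuum Short Form (MHC-SF)
#'
#' Scores a 14-item MHC-SF response vector. Items are monthly symptom
#' frequencies on a 6-point scale from 0 ("never") to 5 ("every day").
#' Items 1--3 assess emotional well-being; items 4--14 assess positive
#' (social + psychological) functioning, following the standard instrument
#' layout.
#'
#' The categorical diagnosis follows the established counting rules:
#' *flourishing* requires a response in the top frequency band (4 "almost
#' every day" or 5 "every day") on at least one emotional item and on at
#' least six of the eleven functioning items; *languishing* requires a
#' bottom-band response (0 "never" or 1 "once or twice") on at least one
#' emotional item and at least six functioning items; everyone else is
#' *moderate*. Because each criterion claims six of the eleven functioning
#' items in opposite bands, the two diagnoses are mutually exclusive.
#' `moderate` and `languishing` are additionally collapsed into
#' `moderate_to_low` for dual-factor classification.
#'
#' @param items numeric vector of length 14, values in `0:5` or `NA`.
#' @param missing_policy `"tolerant"` (default) evaluates the band counts
#'   over answered items only, so unanswered items qualify for neither
#'   band and incomplete responders drift toward `moderate`; `"strict"`
#'   returns `NA` category when any item is missing.
#' @return A list of class `mhc_score` with elements `total` (0--70,
#'   `NA` unless all 14 items answered), the four band counts
#'   (`emotional_high_count`, `functioning_high_count`,
#'   `emotional_low_count`, `functioning_low_count`), subscale totals
#'   (`emotional`, `social`, `psychological`, `NA` if incomplete),
#'   `category` (`"flourishing"`, `"moderate"`, `"languishing"`) and
#'   `collapsed` (`"flourishing"`, `"moderate_to_low"`).
#' @examples
#' score_mhcsf(rep(5, 14))$category   # flourishing
#' score_mhcsf(rep(0, 14))$category   # languishing
#' @export
score_mhcsf <- function(items, missing_policy = c("tolerant", "strict")) {
  missing_policy <- match.arg(missing_policy)
  items <- as.numeric(items)
  if (length(items) != 14L)
    stop("MHC-SF requires exactly 14 item responses, got ", length(items))
  bad <- which(!is.na(items) & (items < 0 | items > 5 | items != floor(items)))
  if (length(bad))
    stop("MHC-SF item ", bad[1L], " out of range 0-5: ", items[bad[1L]])

  emo <- items[1:3]
  fun <- items[4:14]
  complete <- !anyNA(items)

  if (missing_policy == "strict" && !complete) {
    return(structure(list(
      total = NA_real_, emotional_high_count = NA_integer_,
      functioning_high_count = NA_integer_, emotional_low_count = NA_integer_,
      functioning_low_count = NA_integer_, emotional = NA_real_,
      social = NA_real_, psychological = NA_real_,
      category = NA_character_, collapsed = NA_character_,
      n_answered = sum(!is.na(items))), class = "mhc_score"))
  }

  eh <- sum(emo >= 4, na.rm = TRUE)
  fh <- sum(fun >= 4, na.rm = TRUE)
  el <- sum(emo <= 1, na.rm = TRUE)
  fl <- sum(fun <= 1, na.rm = TRUE)

  category <- if (eh >= 1L && fh >= 6L) "flourishing"
  else if (el >= 1L && fl >= 6L) "languishing"
  else "moderate"

  structure(list(
    total = if (complete) sum(items) else NA_real_,
    emotional_high_count = as.integer(eh),
    functioning_high_count = as.integer(fh),
    emotional_low_count = as.integer(el),
    functioning_low_count = as.integer(fl),
    emotional = if (anyNA(emo)) NA_real_ else sum(emo),
    social = if (anyNA(items[4:8])) NA_real_ else sum(items[4:8]),
    psychological = if (anyNA(items[9:14])) NA_real_ else sum(items[9:14]),
    category = category,
    collapsed = if (category == "flourishing") "flourishing" else "moderate_to_low",
    n_answered = sum(!is.na(items))), class = "mhc_score")
}

# Standard SDQ self-report item map (1-based positions in the 25-item form).
# Five subscales of five items; the five positively-worded difficulty items
# (7, 11, 14, 21, 25) are reverse-scored (2 - raw) before summing.
.sdq_subscales <- list(
  emotional     = c(3L, 8L, 13L, 16L, 24L),
  conduct       = c(5L, 7L, 12L, 18L, 22L),
  hyperactivity = c(2L, 10L, 15L, 21L, 25L),
  peer          = c(6L, 11L, 14L, 19L, 23L),
  prosocial     = c(1L, 4L, 9L, 17L, 20L)
)
.sdq_reverse <- c(7L, 11L, 14L, 21L, 25L)

#' Score the Strengths and Difficulties Questionnaire (SDQ)
#'
#' Scores the 25-item self-report SDQ (responses 0 "not true", 1 "somewhat
#' true", 2 "certainly true") into its five subscales. The total
#' difficulties score sums the emotional, conduct, hyperactivity and peer
#' subscales (prosocial excluded), range 0--40, after reverse-scoring the
#' five positively worded difficulty items (positions 7, 11, 14, 21, 25 of
#' the standard form) as `2 - raw`. Caseness (possible mental health
#' problems) is a total difficulties score at or above `cutoff`; the
#' default 20 corresponds to the 90th percentile of a UK population norm.
#'
#' @param items numeric vector of length 25, values in `0:2` or `NA`.
#' @param cutoff caseness cutoff on the total difficulties score
#'   (default 20).
#' @param prorate if `TRUE`, a subscale with at least 3 of 5 items
#'   answered is prorated as `round(5 * mean(answered))`; the default
#'   (`FALSE`) is complete-case: any missing item makes its subscale (and
#'   hence the total) `NA`.
#' @return A list of class `sdq_score` with the five subscale scores,
#'   `total_difficulties` and logical `caseness` (`NA` when the total is
#'   not computable).
#' @examples
#' score_sdq(rep(0, 25))$total_difficulties  # 10: reverse items score 2 each
#' score_sdq(rep(1, 25))$caseness            # TRUE: total 20 hits the cutoff
#' @export
score_sdq <- function(items, cutoff = 20, prorate = FALSE) {
  items <- as.numeric(items)
  if (length(items) != 25L)
    stop("SDQ requires exactly 25 item responses, got ", length(items))
  bad <- which(!is.na(items) & (items < 0 | items > 2 | items != floor(items)))
  if (length(bad))
    stop("SDQ item ", bad[1L], " out of range 0-2: ", items[bad[1L]])

  scored <- items
  scored[.sdq_reverse] <- 2 - scored[.sdq_reverse]

  sub <- vapply(.sdq_subscales, function(idx) {
    x <- scored[idx]
    if (!anyNA(x)) return(sum(x))
    if (prorate && sum(!is.na(x)) >= 3L) return(round(5 * mean(x, na.rm = TRUE)))
    NA_real_
  }, numeric(1))

  total <- unname(sub["emotional"] + sub["conduct"] +
                    sub["hyperactivity"] + sub["peer"])
  structure(list(
    emotional = unname(sub["emotional"]), conduct = unname(sub["conduct"]),
    hyperactivity = unname(sub["hyperactivity"]), peer = unname(sub["peer"]),
    prosocial = unname(sub["prosocial"]),
    total_difficulties = total,
    caseness = if (is.na(total)) NA else total >= cutoff),
    class = "sdq_score")
}

#' Score the CYRM-12 resilience measure
#'
#' Sums the 12 Child and Youth Resilience Measure items (each 1--5), total
#' range 12--60; higher means more resilient. Missing items make the total
#' missing (no prorating, matching listwise handling downstream).
#'
#' @param items numeric vector of length 12, values in `1:5` or `NA`.
#' @return Scalar total, or `NA` if any item is missing.
#' @export
score_cyrm <- function(items) {
  items <- as.numeric(items)
  if (length(items) != 12L)
    stop("CYRM-12 requires exactly 12 item responses, got ", length(items))
  bad <- which(!is.na(items) & (items < 1 | items > 5 | items != floor(items)))
  if (length(bad))
    stop("CYRM item ", bad[1L], " out of range 1-5: ", items[bad[1L]])
  if (anyNA(items)) NA_real_ else sum(items)
}

#' Cronbach's alpha internal consistency
#'
#' Computes Cronbach's alpha, `k/(k-1) * (1 - sum(item variances) /
#' var(row totals))`, on complete-case rows with sample (n-1) variances.
#' Alpha is at most 1 but can be negative for pathological data.
#'
#' @param item_matrix numeric matrix or data frame, respondents in rows,
#'   items in columns (`k >= 2`).
#' @return List of class `reliability` with `alpha`, `k_items`,
#'   `n_complete`.
#' @export
cronbach_alpha <- function(item_matrix) {
  x <- as.matrix(item_matrix)
  if (ncol(x) < 2L) stop("Cronbach's alpha needs at least 2 items")
  x <- x[stats::complete.cases(x), , drop = FALSE]
  n <- nrow(x)
  if (n < 2L) stop("Cronbach's alpha needs at least 2 complete rows, got ", n)
  k <- ncol(x)
  total_var <- stats::var(rowSums(x))
  if (total_var <= 0) stop("Cronbach's alpha undefined: zero variance of row totals")
  item_var <- sum(apply(x, 2, stats::var))
  structure(list(alpha = k / (k - 1) * (1 - item_var / total_var),
                 k_items = k, n_complete = n),
            class = "reliability")
}

#' @export
print.mhc_score <- function(x, ...) {
  cat("MHC-SF: total =", x$total, " category =", x$category,
      "(", x$collapsed, ")\n")
  invisible(x)
}

#' @export
print.sdq_score <- function(x, ...) {
  cat("SDQ: total difficulties =", x$total_difficulties,
      " caseness =", x$caseness, "\n")
  invisible(x)
}

#' @export
print.reliability <- function(x, ...) {
  cat(sprintf("Cronbach's alpha = %.3f (%d items, %d complete rows)\n",
              x$alpha, x$k_items, x$n_complete))
  invisible(x)
}
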