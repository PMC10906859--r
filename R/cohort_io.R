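# Covariate derivation and the exclusion cascade.

.cat_codes <- list(
  gender_raw = c("girl", "boy", "other", "unsure"),
  birth_country_raw = c("sweden", "europe", "world"),
  guardian_a_occupation = c("working", "studying", "unemployed",
                            "longterm_sick", "sick_short", "other", "unknown"),
  guardian_b_occupation = c("working", "studying", "unemployed",
                            "longterm_sick", "sick_short", "other", "unknown",
                            "no_second_guardian"),
  grade_f_raw = c("none", "1-2", "3-4", "5_plus"),
  truancy_raw = c("no", "per_semester", "per_month", "2-3_per_month",
                  "per_week", "several_per_week"),
  stress_raw = c("no", "some_extent", "fairly_much", "very_much")
)

.check_codes <- function(records) {
  for (col in intersect(names(.cat_codes), names(records))) {
    v <- as.character(records[[col]])
    bad <- setdiff(unique(v[!is.na(v)]), .cat_codes[[col]])
    if (length(bad))
      stop("unknown category code in column '", col, "': '", bad[1L], "'")
  }
  invisible(records)
}

# Default variables whose missingness excludes a respondent: the raw
# demographic/school/stress questions plus every CYRM and SDQ item.
# MHC-SF items and the SSS ladder are deliberately absent: incomplete
# MHC responders are still classifiable and missing SSS only shrinks the
# SSS-adjusted regressions.
#' @rdname apply_exclusions
#' @export
default_required_vars <- function() {
  c("gender_raw", "birth_country_raw", "guardian_a_occupation",
    "guardian_b_occupation", "grade", "grade_f_raw", "truancy_raw",
    "stress_raw", paste0("cyrm_", 1:12), paste0("sdq_", 1:25))
}

#' Derive the dichotomised analysis covariates
#'
#' Maps the raw survey responses of a cohort onto the analysis
#' covariates: `gender` girl/boy (other or uncertain identities become
#' `NA`; the cascade removes them upstream); `birth_country`
#' Sweden/other; `guardian_unemployed_or_sickleave` at_least_one if
#' either guardian is unemployed or on long-term sick-leave / retired due
#' to disability; `school_level` lower (grades 7-9) / upper (10-12);
#' `grade_f` at_least_one for an F or no grade in any subject; `truancy`
#' never/ever; `stressed` considerable iff stressed "fairly much" or
#' "very much"; `resilience_score` as the CYRM-12 total (missing if any
#' item missing); `sss` passed through. Missing raw values propagate to
#' missing derived values.
#'
#' @param records cohort data frame with the raw columns.
#' @return Data frame of derived covariates, one row per respondent,
#'   carrying `respondent_id`.
#' @export
derive_covariates <- function(records) {
  .check_codes(records)
  n <- nrow(records)
  ch <- function(col) as.character(records[[col]])
  dicho <- function(x, yes_levels, yes, no)
    ifelse(is.na(x), NA_character_, ifelse(x %in% yes_levels, yes, no))

  gender <- ch("gender_raw")
  gender[!is.na(gender) & !gender %in% c("girl", "boy")] <- NA_character_

  ga <- ch("guardian_a_occupation"); gb <- ch("guardian_b_occupation")
  bad_occ <- c("unemployed", "longterm_sick")
  guardian <- ifelse(is.na(ga) | is.na(gb), NA_character_,
                     ifelse(ga %in% bad_occ | gb %in% bad_occ,
                            "at_least_one", "none"))

  grade <- as.integer(records$grade)
  school <- ifelse(is.na(grade), NA_character_,
                   ifelse(grade <= 9L, "lower", "upper"))

  cyrm_cols <- paste0("cyrm_", 1:12)
  resilience <- if (all(cyrm_cols %in% names(records))) {
    m <- as.matrix(records[, cyrm_cols])
    ifelse(apply(m, 1, anyNA), NA_real_, rowSums(m))
  } else rep(NA_real_, n)

  data.frame(
    respondent_id = records$respondent_id,
    gender = gender,
    birth_country = dicho(ch("birth_country_raw"), "sweden", "sweden", "other"),
    guardian_unemployed_or_sickleave = guardian,
    school_level = school,
    grade_f = dicho(ch("grade_f_raw"), "none", "no_subject", "at_least_one"),
    truancy = dicho(ch("truancy_raw"), "no", "never", "ever"),
    stressed = dicho(ch("stress_raw"), c("fairly_much", "very_much"),
                     "considerable", "no_or_some"),
    resilience_score = resilience,
    sss = if ("sss" %in% names(records)) as.numeric(records$sss) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Apply the exclusion cascade with an audit trail
#'
#' Sequentially removes (1) records whose height or weight lies beyond
#' the mean plus or minus two sample standard deviations, both computed
#' on the full input set (an implausible-response screen); (2) records
#' reporting another or uncertain gender identity; (3) records missing
#' any required analysis variable. Each excluded record is counted once,
#' under the first rule that removed it, and the audit reconciles
#' `n_final = n_input - (outliers + gender + missing)`.
#'
#' Filter (1) is computed on the original input; re-running the cascade
#' on its own output recomputes the bounds on the reduced set and can in
#' principle remove further records, which the audit makes visible rather
#' than hiding.
#'
#' @param records cohort data frame (non-empty, with `height` and
#'   `weight`).
#' @param required_vars character vector of column names whose
#'   missingness excludes a respondent (default
#'   [default_required_vars()]).
#' @return List with `records` (retained rows) and `audit`, a list of
#'   class `exclusion_audit` with the counts, the height/weight bounds
#'   used, and `per_record_reasons` (id -> first reason).
#' @examples
#' cohort <- generate_cohort(sim_config(n_respondents = 300, seed = 9))
#' apply_exclusions(cohort)$audit
#' @export
apply_exclusions <- function(records, required_vars = default_required_vars()) {
  if (nrow(records) == 0L) stop("cannot apply exclusions to an empty cohort")
  if (!all(c("height", "weight") %in% names(records)))
    stop("records must contain height and weight columns")
  missing_cols <- setdiff(required_vars, names(records))
  if (length(missing_cols))
    stop("required variable not present in records: ", missing_cols[1L])
  .check_codes(records)

  n_input <- nrow(records)
  id <- as.character(records$respondent_id)
  reasons <- character(0)

  bounds <- lapply(records[, c("height", "weight")], function(x) {
    m <- mean(x, na.rm = TRUE); s <- stats::sd(x, na.rm = TRUE)
    c(lower = m - 2 * s, upper = m + 2 * s)
  })
  out_hw <- with(bounds, (records$height < height["lower"] |
                            records$height > height["upper"] |
                            records$weight < weight["lower"] |
                            records$weight > weight["upper"]))
  out_hw[is.na(out_hw)] <- FALSE
  reasons[id[out_hw]] <- "heightweight_outlier"
  keep1 <- !out_hw

  gender_excl <- keep1 & records$gender_raw %in% c("other", "unsure")
  reasons[id[gender_excl]] <- "gender_other_or_unsure"
  keep2 <- keep1 & !gender_excl

  miss <- apply(is.na(records[, required_vars, drop = FALSE]), 1, any)
  miss_excl <- keep2 & miss
  reasons[id[miss_excl]] <- "missing_required"
  keep3 <- keep2 & !miss_excl

  audit <- structure(list(
    n_input = n_input,
    n_heightweight_outliers = sum(out_hw),
    n_gender_other_or_unsure = sum(gender_excl),
    n_missing_required = sum(miss_excl),
    n_final = sum(keep3),
    bounds = bounds,
    sd_type = "sample (n-1)",
    per_record_reasons = reasons), class = "exclusion_audit")
  stopifnot(audit$n_final == n_input - audit$n_heightweight_outliers -
              audit$n_gender_other_or_unsure - audit$n_missing_required)
  list(records = records[keep3, , drop = FALSE], audit = audit)
}

#' @export
print.exclusion_audit <- function(x, ...) {
  cat("Exclusion cascade:\n")
  cat(sprintf("  input                     %6d\n", x$n_input))
  cat(sprintf("  - height/weight outliers  %6d\n", x$n_heightweight_outliers))
  cat(sprintf("  - gender other/unsure     %6d\n", x$n_gender_other_or_unsure))
  cat(sprintf("  - missing required        %6d\n", x$n_missing_required))
  cat(sprintf("  = final                   %6d\n", x$n_final))
  invisible(x)
}

#' Score a cohort's instruments and classify dual-factor status
#'
#' Runs [score_mhcsf()], [score_sdq()], [score_cyrm()] and
#' [classify_status()] over every respondent and binds the results to the
#' derived covariates.
#'
#' @param records cohort data frame with `mhc_1..14`, `sdq_1..25`,
#'   `cyrm_1..12` columns.
#' @param mhc_missing_policy passed to [score_mhcsf()].
#' @param sdq_cutoff,sdq_prorate passed to [score_sdq()].
#' @return Data frame: derived covariates plus `mhc_total`,
#'   `mhc_category`, `mhc_collapsed`, `sdq_total`, `sdq_caseness`, and
#'   `status`.
#' @export
score_cohort <- function(records, mhc_missing_policy = "tolerant",
                         sdq_cutoff = 20, sdq_prorate = FALSE) {
  cov <- derive_covariates(records)
  mhc_m <- as.matrix(records[, paste0("mhc_", 1:14)])
  sdq_m <- as.matrix(records[, paste0("sdq_", 1:25)])

  mhc <- apply(mhc_m, 1, score_mhcsf, missing_policy = mhc_missing_policy)
  sdq <- apply(sdq_m, 1, score_sdq, cutoff = sdq_cutoff, prorate = sdq_prorate)

  cov$mhc_total <- vapply(mhc, `[[`, numeric(1), "total")
  cov$mhc_category <- vapply(mhc, `[[`, character(1), "category")
  cov$mhc_collapsed <- vapply(mhc, `[[`, character(1), "collapsed")
  cov$sdq_total <- vapply(sdq, `[[`, numeric(1), "total_difficulties")
  cov$sdq_caseness <- vapply(sdq, function(s)
    if (is.na(s$total_difficulties)) NA else s$caseness, logical(1))
  cov$status <- classify_status(cov$mhc_collapsed, cov$sdq_caseness)
  cov
}
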