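# Pipeline orchestration: exclude -> score -> classify -> compare -> regress.

.group_order <- c("complete", "symptomatic_but_content", "vulnerable", "troubled")

# Categorical analysis variables compared across status groups, with the
# level treated as the "exposure" in effect sizes and regressions and the
# reference level (first) for logistic coding.
.cat_variables <- list(
  gender = list(ref = "boy", exposure = "girl"),
  birth_country = list(ref = "sweden", exposure = "other"),
  guardian_unemployed_or_sickleave = list(ref = "none", exposure = "at_least_one"),
  school_level = list(ref = "lower", exposure = "upper"),
  grade_f = list(ref = "no_subject", exposure = "at_least_one"),
  truancy = list(ref = "never", exposure = "ever"),
  stressed = list(ref = "no_or_some", exposure = "considerable")
)
.cont_variables <- c("resilience_score", "sss")

#' Run the full dual-factor analysis pipeline
#'
#' Orchestrates the complete analysis on a respondent-level cohort:
#' exclusion cascade, instrument scoring, dual-factor classification,
#' group comparisons and logistic regressions, emitting analogues of the
#' customary report tables plus a reproducibility manifest.
#'
#' @param records respondent-level cohort data frame (e.g. from
#'   [generate_cohort()] or [read_cohort()]).
#' @param apply_exclusions run the exclusion cascade first (default
#'   `TRUE`).
#' @param required_vars passed to [apply_exclusions()].
#' @param sdq_cutoff SDQ caseness cutoff (default 20).
#' @param multivariable fit the adjusted vulnerable-vs-complete model
#'   (default `TRUE`); restricted to respondents with complete SSS.
#' @param m_tests Bonferroni divisor; `NULL` (default) counts the tests
#'   this run performs, or pin a fixed value for parity with an external
#'   analysis plan.
#' @param alpha family-wise error rate (default 0.05).
#' @return Object of class `dfm_report`: list with `descriptives`
#'   (per-variable n/percent), `instruments` (summary + reliability),
#'   `status` ([tabulate_status()] result), `group_comparisons` (one
#'   entry per variable: omnibus test + pairwise effect sizes),
#'   `univariate` (per predictor x outcome OR table), `multivariable`
#'   (adjusted fit, HL test, VIF screen), `threshold` (Bonferroni), and
#'   `manifest` (n at every stage, warnings).
#' @export
run_pipeline <- function(records, apply_exclusions = TRUE,
                         required_vars = default_required_vars(),
                         sdq_cutoff = 20, multivariable = TRUE,
                         m_tests = NULL, alpha = 0.05) {
  manifest <- list(n_input = nrow(records), warnings = character(0),
                   stages = list())
  audit <- NULL
  if (apply_exclusions) {
    ex <- apply_exclusions(records, required_vars)
    records <- ex$records
    audit <- ex$audit
  }
  manifest$stages$after_exclusions <- nrow(records)

  scored <- score_cohort(records, sdq_cutoff = sdq_cutoff)
  manifest$stages$scored <- nrow(scored)

  # ---- Table 2 shape: descriptives -----------------------------------
  desc <- list()
  for (v in names(.cat_variables)) {
    tab <- table(scored[[v]], useNA = "no")
    desc[[v]] <- data.frame(category = names(tab), n = as.integer(tab),
                            percent = round_half_up(100 * as.integer(tab) /
                                                      sum(tab), 1))
  }
  for (v in .cont_variables) {
    x <- scored[[v]]
    desc[[v]] <- data.frame(category = "mean_sd",
                            n = sum(!is.na(x)),
                            mean = mean(x, na.rm = TRUE),
                            sd = stats::sd(x, na.rm = TRUE))
  }

  # ---- Table 3 shape: instrument summaries ---------------------------
  summarize_scale <- function(x) {
    x <- x[!is.na(x)]
    data.frame(n = length(x), mean = mean(x), sd = stats::sd(x),
               median = stats::median(x),
               p10 = stats::quantile(x, 0.10, type = 7, names = FALSE),
               p90 = stats::quantile(x, 0.90, type = 7, names = FALSE))
  }
  mhc_band <- table(factor(scored$mhc_collapsed,
                           c("flourishing", "moderate_to_low")))
  sdq_band <- table(factor(scored$sdq_caseness, c(TRUE, FALSE),
                           labels = c("problems", "no_problems")))
  instruments <- list(
    mhc = summarize_scale(scored$mhc_total),
    sdq = summarize_scale(scored$sdq_total),
    mhc_bands = data.frame(band = names(mhc_band), n = as.integer(mhc_band),
                           percent = round_half_up(100 * as.integer(mhc_band) /
                                                     sum(mhc_band), 1)),
    sdq_bands = data.frame(band = names(sdq_band), n = as.integer(sdq_band),
                           percent = round_half_up(100 * as.integer(sdq_band) /
                                                     sum(sdq_band), 1)),
    reliability = list(
      mhc = tryCatch(cronbach_alpha(records[, paste0("mhc_", 1:14)]),
                     error = function(e) NULL),
      sdq = tryCatch({
        sc <- records[, paste0("sdq_", 1:25)]
        sc[, .sdq_reverse] <- 2 - sc[, .sdq_reverse]
        cronbach_alpha(sc[, setdiff(1:25, .sdq_subscales$prosocial)])
      }, error = function(e) NULL),
      cyrm = tryCatch(cronbach_alpha(records[, paste0("cyrm_", 1:12)]),
                      error = function(e) NULL)),
    spearman_mhc_sdq = tryCatch(spearman_rho(scored$mhc_total, scored$sdq_total),
                                error = function(e) NA_real_))

  # ---- Table 4 shape: status distribution ----------------------------
  status_dist <- tabulate_status(scored$status)
  manifest$stages$classified <- status_dist$n_classified

  # ---- Table 5 shape: group comparisons ------------------------------
  n_tests <- 0L
  comparisons <- list()
  for (v in names(.cat_variables)) {
    exposure <- .cat_variables[[v]]$exposure
    ok <- !is.na(scored[[v]]) & !is.na(scored$status)
    tab <- table(scored[[v]][ok], scored$status[ok])
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    omni <- tryCatch(crosstab_test(t(tab)), error = function(e) NULL)
    if (is.null(omni)) next
    n_tests <- n_tests + 1L
    succ <- tab[exposure, ]
    tot <- colSums(tab)
    comparisons[[v]] <- list(variable = v, type = "categorical",
                             counts = tab, omnibus = omni,
                             pairwise = pairwise_proportions(succ, tot,
                                                            colnames(tab)))
  }
  for (v in .cont_variables) {
    ok <- !is.na(scored[[v]]) & !is.na(scored$status)
    fit <- tryCatch(anova_tukey(scored[[v]][ok], scored$status[ok]),
                    error = function(e) NULL)
    if (is.null(fit)) next
    n_tests <- n_tests + 1L
    gs <- fit$group_summary
    pairs <- utils::combn(nrow(gs), 2)
    eff <- data.frame(
      group1 = gs$group[pairs[1, ]], group2 = gs$group[pairs[2, ]],
      cohens_d = apply(pairs, 2, function(ij)
        cohens_d(gs$mean[ij[1]], gs$sd[ij[1]], gs$mean[ij[2]], gs$sd[ij[2]])))
    comparisons[[v]] <- list(variable = v, type = "continuous",
                             summary = gs, omnibus = fit, pairwise = eff)
  }

  # ---- Table 6 shape: univariate logistic regressions ----------------
  univariate <- list()
  targets <- c("symptomatic_but_content", "vulnerable", "troubled")
  predictors <- c(names(.cat_variables), .cont_variables)
  for (target in targets) {
    sub <- scored[!is.na(scored$status) &
                    scored$status %in% c("complete", target), ]
    sub$outcome <- sub$status == target
    rows <- list()
    for (v in predictors) {
      d <- sub[!is.na(sub[[v]]), ]
      if (v %in% names(.cat_variables)) {
        d$x <- as.numeric(d[[v]] == .cat_variables[[v]]$exposure)
      } else d$x <- d[[v]]
      fit <- tryCatch(fit_logistic(outcome ~ x, d, hosmer_lemeshow = FALSE),
                      error = function(e) NULL)
      if (is.null(fit)) {
        manifest$warnings <- c(manifest$warnings,
                               paste0("univariate fit failed: ", v, " ~ ", target))
        next
      }
      n_tests <- n_tests + 1L
      t1 <- fit$terms[1, ]
      rows[[v]] <- data.frame(predictor = v, or = t1$or,
                              ci_lower = t1$ci_lower, ci_upper = t1$ci_upper,
                              p_value = t1$p_value,
                              nagelkerke_r2 = fit$nagelkerke_r2,
                              n = fit$n_used)
    }
    univariate[[target]] <- do.call(rbind, c(rows, make.row.names = FALSE))
  }

  # ---- Table 7 shape: adjusted vulnerable-vs-complete model ----------
  multi <- NULL
  if (multivariable) {
    sub <- scored[!is.na(scored$status) &
                    scored$status %in% c("complete", "vulnerable"), ]
    sub$outcome <- sub$status == "vulnerable"
    for (v in names(.cat_variables))
      sub[[paste0(v, "_x")]] <- as.numeric(sub[[v]] ==
                                             .cat_variables[[v]]$exposure)
    form <- stats::as.formula(paste(
      "outcome ~", paste(c(paste0(names(.cat_variables), "_x"),
                           .cont_variables), collapse = " + ")))
    cc <- stats::complete.cases(sub[, c(paste0(names(.cat_variables), "_x"),
                                        .cont_variables)])
    dsub <- sub[cc, ]
    multi <- tryCatch({
      fit <- fit_logistic(form, dsub, hosmer_lemeshow = TRUE)
      n_tests <- n_tests + nrow(fit$terms)
      vif <- vif_screen(dsub[, c(paste0(names(.cat_variables), "_x"),
                                 .cont_variables)])
      list(fit = fit, vif = vif, n = fit$n_used)
    }, error = function(e) {
      manifest$warnings <<- c(manifest$warnings,
                              paste0("multivariable fit failed: ",
                                     conditionMessage(e)))
      NULL
    })
  }

  if (is.null(m_tests)) m_tests <- max(1L, n_tests)
  threshold <- bonferroni_threshold(alpha, m_tests)
  manifest$m_tests <- m_tests
  manifest$threshold <- threshold

  structure(list(audit = audit, scored = scored, descriptives = desc,
                 instruments = instruments, status = status_dist,
                 group_comparisons = comparisons, univariate = univariate,
                 multivariable = multi, threshold = threshold,
                 manifest = manifest),
            class = "dfm_report")
}

#' @export
print.dfm_report <- function(x, ...) {
  cat("== Dual-factor mental health analysis ==\n")
  if (!is.null(x$audit)) print(x$audit)
  print(x$status)
  cat(sprintf("MHC-SDQ Spearman correlation: %.2f\n",
              x$instruments$spearman_mhc_sdq))
  cat(sprintf("Bonferroni threshold: alpha/%d = %.4f\n",
              x$manifest$m_tests, round_half_up(x$threshold, 4)))
  sig <- vapply(x$group_comparisons,
                function(cmp) cmp$omnibus$p_value < x$threshold, logical(1))
  cat("Group differences significant at the corrected threshold:\n  ",
      paste(names(sig)[sig], collapse = ", "), "\n")
  if (!is.null(x$multivariable)) {
    cat("Adjusted vulnerable-vs-complete model:\n")
    print(x$multivariable$fit)
  }
  if (length(x$manifest$warnings))
    cat("Warnings:\n ", paste(x$manifest$warnings, collapse = "\n  "), "\n")
  invisible(x)
}

#' @export
summary.dfm_report <- function(object, ...) print(object)

#' Write the report tables as TSV files
#'
#' Emits one TSV per table shape (descriptives, instruments, status,
#' comparisons, univariate ORs, multivariable ORs) plus a JSON manifest.
#'
#' @param report a `dfm_report` from [run_pipeline()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(df, name) {
    p <- file.path(out_dir, paste0(name, ".tsv"))
    utils::write.table(df, p, sep = "\t", row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  # descriptive rows have heterogeneous columns; fill the union
  allcols <- c("variable", "category", "n", "percent", "mean", "sd")
  desc <- do.call(rbind, lapply(names(report$descriptives), function(v) {
    d <- report$descriptives[[v]]; d$variable <- v
    for (cn in setdiff(allcols, names(d))) d[[cn]] <- NA
    d[, allcols]
  }))
  w(desc, "table2_descriptives")
  w(data.frame(status = names(report$status$counts),
               n = report$status$counts,
               percent = report$status$proportions), "table4_status")
  uni <- do.call(rbind, lapply(names(report$univariate), function(tg)
    cbind(outcome = tg, report$univariate[[tg]])))
  w(uni, "table6_univariate")
  if (!is.null(report$multivariable))
    w(report$multivariable$fit$terms, "table7_multivariable")
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(c(paths, file.path(out_dir, "manifest.json")))
}
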