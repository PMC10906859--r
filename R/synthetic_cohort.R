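# Synthetic survey-cohort generator.
#
# A bivariate-normal latent (well-being W, problems P) trait pair with
# configurable negative correlation drives all instrument responses
# through a Gaussian copula: each item is the latent plus independent
# Gaussian noise, cut at fixed instrument-specific thresholds
# (graded-response style). Covariates shift the latents; missingness and
# height/weight outliers are injected on top.

.default_marginals <- list(
  grade = c("7" = 0.145, "8" = 0.213, "9" = 0.207,
            "10" = 0.149, "11" = 0.172, "12" = 0.114),
  birth_country_raw = c(sweden = 0.927, europe = 0.043, world = 0.030),
  guardian_a_occupation = c(working = 0.906, studying = 0.027,
                            unemployed = 0.016, longterm_sick = 0.011,
                            sick_short = 0.013, other = 0.014, unknown = 0.013),
  guardian_b_occupation = c(working = 0.845, studying = 0.027,
                            unemployed = 0.021, longterm_sick = 0.016,
                            sick_short = 0.020, other = 0.023, unknown = 0.028,
                            no_second_guardian = 0.020),
  grade_f_raw = c(none = 0.794, "1-2" = 0.140, "3-4" = 0.040, "5_plus" = 0.026),
  truancy_raw = c(no = 0.708, per_semester = 0.150, per_month = 0.060,
                  "2-3_per_month" = 0.042, per_week = 0.025,
                  several_per_week = 0.015),
  stress_raw = c(no = 0.200, some_extent = 0.381,
                 fairly_much = 0.270, very_much = 0.149)
)

.default_effects <- list(
  stress = list(variable = "stress_raw",
                levels = c("fairly_much", "very_much"),
                wellbeing = -0.55, problems = 0.75),
  truancy = list(variable = "truancy_raw",
                 levels = c("per_month", "2-3_per_month", "per_week",
                            "several_per_week"),
                 wellbeing = -0.15, problems = 0.30),
  grade_f = list(variable = "grade_f_raw",
                 levels = c("1-2", "3-4", "5_plus"),
                 wellbeing = -0.10, problems = 0.30)
)

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every parameter of [generate_cohort()]. Defaults
#' are calibrated once so that a default cohort resembles a Swedish
#' secondary-school survey population: covariate marginals near the
#' published descriptive frequencies, about 38% flourishing, about 16%
#' SDQ caseness, and an observed MHC-SDQ Spearman correlation near -0.50
#' (the latent correlation -0.55 allows for discretisation loss).
#'
#' @param n_respondents number of records to generate.
#' @param latent_correlation correlation of the latent (well-being,
#'   problems) pair, in (-1, 1).
#' @param gender_split proportion of girls among girl/boy respondents.
#' @param gender_other_rate proportion reporting another or uncertain
#'   gender identity (excluded downstream by the analysis cascade).
#' @param gender_effect_wellbeing,gender_effect_problems latent-scale
#'   shifts applied to girls.
#' @param covariate_marginals named list of category-probability vectors
#'   for the raw categorical survey variables; each must sum to 1.
#' @param covariate_effects named list of effects, each a list with
#'   `variable`, `levels` (categories that trigger the shift),
#'   `wellbeing` and `problems` shifts.
#' @param item_thresholds list of cut-point vectors `mhc` (5 cuts, items
#'   0-5), `sdq` (2 cuts, items 0-2), `cyrm` (4 cuts, items 1-5) on the
#'   latent-plus-noise scale.
#' @param item_noise_sd named vector (`mhc`, `sdq`, `cyrm`) of per-item
#'   independent Gaussian noise SDs (a scalar is recycled). The defaults
#'   are calibrated so each instrument's internal consistency lands near
#'   its published value (alpha about 0.91, 0.74 and 0.75).
#' @param resilience_loading,sss_loading correlation loadings of the
#'   resilience and subjective-social-status latents on well-being.
#' @param missing_rate_mhc per-item missingness rate for MHC-SF items.
#' @param missing_rate_sss missingness rate for the SSS ladder.
#' @param missing_rate_required rate of records given a missing value on
#'   one randomly chosen required analysis variable (default 0).
#' @param outlier_rate_heightweight rate of injected implausible
#'   height/weight records (beyond 2.6-4 SD).
#' @param seed integer root seed; all draws derive from it.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_respondents = 2208,
                       latent_correlation = -0.55,
                       gender_split = 0.50,
                       gender_other_rate = 0.027,
                       gender_effect_wellbeing = -0.30,
                       gender_effect_problems = 0.55,
                       covariate_marginals = .default_marginals,
                       covariate_effects = .default_effects,
                       item_thresholds = list(
                         mhc = c(-2.76, -1.88, -1.05, -0.17, 0.93),
                         sdq = c(0.54, 3.47),
                         cyrm = c(-4.12, -2.85, -1.30, 1.15)),
                       item_noise_sd = c(mhc = 1.15, sdq = 2.40, cyrm = 1.95),
                       resilience_loading = 0.60,
                       sss_loading = 0.45,
                       missing_rate_mhc = 0.009,
                       missing_rate_sss = 0.109,
                       missing_rate_required = 0,
                       outlier_rate_heightweight = 0.011,
                       seed = 1L) {
  cfg <- list(n_respondents = n_respondents,
              latent_correlation = latent_correlation,
              gender_split = gender_split,
              gender_other_rate = gender_other_rate,
              gender_effect_wellbeing = gender_effect_wellbeing,
              gender_effect_problems = gender_effect_problems,
              covariate_marginals = covariate_marginals,
              covariate_effects = covariate_effects,
              item_thresholds = item_thresholds,
              item_noise_sd = if (length(item_noise_sd) == 1L)
                c(mhc = unname(item_noise_sd), sdq = unname(item_noise_sd),
                  cyrm = unname(item_noise_sd)) else item_noise_sd,
              resilience_loading = resilience_loading,
              sss_loading = sss_loading,
              missing_rate_mhc = missing_rate_mhc,
              missing_rate_sss = missing_rate_sss,
              missing_rate_required = missing_rate_required,
              outlier_rate_heightweight = outlier_rate_heightweight,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stop_field <- function(field, msg)
    stop("invalid sim_config field '", field, "': ", msg, call. = FALSE)
  if (!is.numeric(cfg$n_respondents) || cfg$n_respondents < 0 ||
      cfg$n_respondents != floor(cfg$n_respondents))
    stop_field("n_respondents", "must be a non-negative integer")
  if (abs(cfg$latent_correlation) >= 1)
    stop_field("latent_correlation", "must lie strictly in (-1, 1)")
  for (f in c("gender_split", "gender_other_rate", "missing_rate_mhc",
              "missing_rate_sss", "missing_rate_required",
              "outlier_rate_heightweight")) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v >= 1) stop_field(f, "must lie in [0, 1)")
  }
  if (cfg$gender_split <= 0) stop_field("gender_split", "must lie in (0, 1)")
  for (nm in names(cfg$covariate_marginals)) {
    p <- cfg$covariate_marginals[[nm]]
    if (any(p < 0) || any(p > 1))
      stop_field(paste0("covariate_marginals$", nm), "probabilities outside [0, 1]")
    if (abs(sum(p) - 1) > 1e-9)
      stop_field(paste0("covariate_marginals$", nm),
                 sprintf("probabilities sum to %.12f, not 1", sum(p)))
    if (is.null(names(p))) stop_field(paste0("covariate_marginals$", nm),
                                      "categories must be named")
  }
  if (any(cfg$item_noise_sd <= 0)) stop_field("item_noise_sd", "must be positive")
  lens <- c(mhc = 5L, sdq = 2L, cyrm = 4L)
  for (nm in names(lens)) {
    cuts <- cfg$item_thresholds[[nm]]
    if (length(cuts) != lens[[nm]] || is.unsorted(cuts))
      stop_field(paste0("item_thresholds$", nm),
                 sprintf("must be %d increasing cut points", lens[[nm]]))
  }
  invisible(cfg)
}

# Cut a latent+noise draw into ordinal scores starting at `base`.
.discretize <- function(x, cuts, base = 0L) {
  base + findInterval(x, cuts)
}


#' Generate a synthetic survey cohort
#'
#' Draws `n_respondents` respondent-level records with the dependence
#' structure the dual-factor analysis assumes: a bivariate-normal latent
#' (well-being, problems) pair with correlation
#' `latent_correlation`, shifted by gender and covariate effects, then
#' discretised into MHC-SF, SDQ and CYRM-12 item responses through fixed
#' thresholds plus per-item Gaussian noise. SSS, height and weight,
#' missingness, and implausible height/weight outliers are layered on
#' top. Identical configurations (including the seed) give identical
#' cohorts.
#'
#' Injected exclusion features (outliers, other/unsure gender, missing
#' required variables) are placed on deterministic counts
#' (`round(rate * n)`) over disjoint record sets, so a configured cascade
#' reproduces its exclusion arithmetic exactly.
#'
#' @param config a [sim_config()] object.
#' @return Data frame with one row per respondent: `respondent_id`,
#'   `gender_raw`, `grade`, raw categorical covariates, `mhc_1..14`,
#'   `sdq_1..25`, `cyrm_1..12`, `sss`, `height`, `weight`, plus the
#'   latent traits as attribute `latents` (for calibration diagnostics).
#' @examples
#' cohort <- generate_cohort(sim_config(n_respondents = 200, seed = 42))
#' nrow(cohort)
#' @export
generate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  validate_sim_config(config)
  n <- config$n_respondents
  cols <- c("respondent_id", "gender_raw", "grade", "birth_country_raw",
            "guardian_a_occupation", "guardian_b_occupation", "grade_f_raw",
            "truancy_raw", "stress_raw",
            paste0("mhc_", 1:14), paste0("sdq_", 1:25), paste0("cyrm_", 1:12),
            "sss", "height", "weight")
  if (n == 0L) {
    empty <- as.data.frame(stats::setNames(rep(list(logical(0)), length(cols)), cols))
    return(empty)
  }
  set.seed(config$seed)

  # gender: deterministic count of other/unsure, random girl/boy split
  n_other <- round(config$gender_other_rate * n)
  gender <- ifelse(stats::runif(n) < config$gender_split, "girl", "boy")
  other_idx <- if (n_other > 0) sample.int(n, n_other) else integer(0)
  gender[other_idx] <- sample(c("other", "unsure"), n_other, replace = TRUE)

  # categorical covariates, independent given gender
  draw_cat <- function(p) names(p)[sample.int(length(p), n, replace = TRUE, prob = p)]
  cov <- lapply(config$covariate_marginals, draw_cat)
  grade <- as.integer(cov$grade)

  # latent bivariate normal (W, P)
  rho <- config$latent_correlation
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  W <- z1
  P <- rho * z1 + sqrt(1 - rho^2) * z2
  girl <- gender == "girl"
  W <- W + config$gender_effect_wellbeing * girl
  P <- P + config$gender_effect_problems * girl
  for (eff in config$covariate_effects) {
    hit <- cov[[eff$variable]] %in% eff$levels
    W <- W + eff$wellbeing * hit
    P <- P + eff$problems * hit
  }

  noise <- config$item_noise_sd
  cuts <- config$item_thresholds

  mhc <- vapply(1:14, function(i)
    .discretize(W + stats::rnorm(n, sd = noise[["mhc"]]), cuts$mhc, 0L),
    integer(n))
  mhc <- matrix(mhc, nrow = n)

  # SDQ: 20 difficulty items driven by P; 5 prosocial items mildly
  # anti-correlated with P. Reverse-worded difficulty items are stored as
  # raw = 2 - scored so standard scoring recovers the intended level.
  prosocial_pos <- .sdq_subscales$prosocial
  sdq <- matrix(NA_integer_, n, 25)
  for (i in 1:25) {
    if (i %in% prosocial_pos) {
      sdq[, i] <- .discretize(-0.3 * P + stats::rnorm(n, sd = noise[["sdq"]]),
                              cuts$sdq, 0L)
    } else {
      scored <- .discretize(P + stats::rnorm(n, sd = noise[["sdq"]]), cuts$sdq, 0L)
      sdq[, i] <- if (i %in% .sdq_reverse) 2L - scored else scored
    }
  }

  rl <- config$resilience_loading
  R <- rl * W + sqrt(1 - rl^2) * stats::rnorm(n)
  cyrm <- vapply(1:12, function(i)
    .discretize(R + stats::rnorm(n, sd = noise[["cyrm"]]), cuts$cyrm, 1L),
    integer(n))
  cyrm <- matrix(cyrm, nrow = n)

  sl <- config$sss_loading
  S <- sl * W + sqrt(1 - sl^2) * stats::rnorm(n)
  sss <- pmin(10L, pmax(1L, as.integer(round(6.8 + 1.8 * S))))

  # height/weight: bounded plausible adolescent ranges (max deviation
  # sqrt(3) SDs), so the empirical 2-SD screening rule flags exactly the
  # injected outliers and nothing else
  height <- stats::runif(n, 155, 179)      # centre 167, SD ~6.9
  weight <- stats::runif(n, 41, 75)        # centre 58,  SD ~9.8
  n_out <- round(config$outlier_rate_heightweight * n)
  outlier_idx <- integer(0)
  if (n_out > 0) {
    pool <- setdiff(seq_len(n), other_idx)
    outlier_idx <- sample(pool, n_out)
    sgn <- rep_len(c(1, -1), n_out)   # alternate signs: no net mean shift
    mag <- stats::runif(n_out, 2.6, 4)
    on_height <- rep_len(c(TRUE, FALSE), n_out)
    height[outlier_idx[on_height]] <- 167 + sgn[on_height] * mag[on_height] * 6.93
    weight[outlier_idx[!on_height]] <- 58 + sgn[!on_height] * mag[!on_height] * 9.81
  }

  # missingness: MCAR per MHC item and on the SSS ladder
  if (config$missing_rate_mhc > 0)
    mhc[matrix(stats::runif(n * 14) < config$missing_rate_mhc, n, 14)] <- NA_integer_
  if (config$missing_rate_sss > 0)
    sss[stats::runif(n) < config$missing_rate_sss] <- NA_integer_

  out <- data.frame(respondent_id = sprintf("r%05d", seq_len(n)),
                    gender_raw = gender, grade = grade,
                    birth_country_raw = cov$birth_country_raw,
                    guardian_a_occupation = cov$guardian_a_occupation,
                    guardian_b_occupation = cov$guardian_b_occupation,
                    grade_f_raw = cov$grade_f_raw,
                    truancy_raw = cov$truancy_raw,
                    stress_raw = cov$stress_raw,
                    stringsAsFactors = FALSE)
  colnames(mhc) <- paste0("mhc_", 1:14)
  colnames(sdq) <- paste0("sdq_", 1:25)
  colnames(cyrm) <- paste0("cyrm_", 1:12)
  out <- cbind(out, mhc, sdq, cyrm)
  out$sss <- sss
  out$height <- height
  out$weight <- weight

  # missing-required injection, disjoint from outlier and gender sets
  n_req <- round(config$missing_rate_required * n)
  if (n_req > 0) {
    pool <- setdiff(seq_len(n), union(other_idx, outlier_idx))
    if (length(pool) < n_req)
      stop("missing_rate_required too high for disjoint injection")
    req_idx <- sample(pool, n_req)
    req_cols <- sample(c("stress_raw", "truancy_raw", "grade_f_raw",
                         "sdq_1", "cyrm_1"), n_req, replace = TRUE)
    for (k in seq_len(n_req)) out[req_idx[k], req_cols[k]] <- NA
  }

  attr(out, "latents") <- data.frame(wellbeing = W, problems = P)
  out
}

#' Compare configured and realised covariate marginals
#'
#' For every categorical marginal named in the configuration, tabulates
#' the realised category frequencies of a generated cohort (on
#' non-missing values) against their targets. A configured marginal whose
#' column is absent from the records is omitted with a warning.
#'
#' @param records cohort data frame from [generate_cohort()].
#' @param config the [sim_config()] used (or one with target marginals).
#' @return Data frame with columns `variable`, `category`, `target`,
#'   `realized`, `abs_error`.
#' @export
calibration_report <- function(records, config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (nrow(records) == 0L) stop("cannot calibrate against an empty cohort")
  rows <- list()
  for (nm in names(config$covariate_marginals)) {
    if (!nm %in% names(records)) {
      warning("configured marginal '", nm, "' not present in records; row omitted")
      next
    }
    target <- config$covariate_marginals[[nm]]
    obs <- as.character(records[[nm]])
    obs <- obs[!is.na(obs)]
    realized <- vapply(names(target),
                       function(cat) mean(obs == cat), numeric(1))
    rows[[nm]] <- data.frame(variable = nm, category = names(target),
                             target = as.numeric(target),
                             realized = realized,
                             abs_error = abs(realized - as.numeric(target)),
                             row.names = NULL)
  }
  do.call(rbind, rows)
}

#' Write a cohort to CSV with a JSON configuration sidecar
#'
#' @param records cohort data frame.
#' @param path output CSV path; the sidecar is written next to it as
#'   `<path>.config.json`.
#' @param config optional [sim_config()] echoed into the sidecar.
#' @return Invisibly, the CSV path.
#' @export
write_cohort <- function(records, path, config = NULL) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE, na = "")
  if (!is.null(config))
    jsonlite::write_json(unclass(config), paste0(path, ".config.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a cohort CSV written by [write_cohort()]
#'
#' @param path CSV path.
#' @return Cohort data frame.
#' @export
read_cohort <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  na.strings = c("", "NA"),
                  colClasses = c(respondent_id = "character"))
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0("sim_config: n = %d, latent correlation = %.2f, ",
                     "girls = %.2f, seed = %d\n"),
              x$n_respondents, x$latent_correlation, x$gender_split, x$seed))
  invisible(x)
}
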