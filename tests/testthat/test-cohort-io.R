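make_record <- function(...) {
  co <- generate_cohort(sim_config(n_respondents = 1, seed = 1,
                                   missing_rate_mhc = 0, missing_rate_sss = 0))
  args <- list(...)
  for (nm in names(args)) co[[nm]] <- args[[nm]]
  co
}

test_that("covariate derivation dichotomises exactly as specified", {
  r <- make_record(stress_raw = "fairly_much", truancy_raw = "per_semester",
                   grade_f_raw = "1-2", birth_country_raw = "europe",
                   guardian_a_occupation = "working",
                   guardian_b_occupation = "longterm_sick",
                   grade = 10L, gender_raw = "girl")
  d <- derive_covariates(r)
  expect_equal(d$stressed, "considerable")
  expect_equal(d$truancy, "ever")
  expect_equal(d$grade_f, "at_least_one")
  expect_equal(d$birth_country, "other")
  expect_equal(d$guardian_unemployed_or_sickleave, "at_least_one")
  expect_equal(d$school_level, "upper")
  expect_equal(d$gender, "girl")

  r2 <- make_record(stress_raw = "some_extent", truancy_raw = "no",
                    grade_f_raw = "none", birth_country_raw = "sweden",
                    guardian_a_occupation = "unknown",
                    guardian_b_occupation = "no_second_guardian", grade = 9L)
  d2 <- derive_covariates(r2)
  expect_equal(d2$stressed, "no_or_some")
  expect_equal(d2$truancy, "never")
  expect_equal(d2$grade_f, "no_subject")
  expect_equal(d2$birth_country, "sweden")
  expect_equal(d2$guardian_unemployed_or_sickleave, "none")
  expect_equal(d2$school_level, "lower")
})

test_that("resilience totals and missingness propagate", {
  r <- make_record()
  r[, paste0("cyrm_", 1:12)] <- as.list(rep(5L, 12))
  expect_equal(derive_covariates(r)$resilience_score, 60)
  r$cyrm_4 <- NA_integer_
  expect_true(is.na(derive_covariates(r)$resilience_score))
  r2 <- make_record(stress_raw = NA_character_)
  expect_true(is.na(derive_covariates(r2)$stressed))
})

test_that("unknown category codes raise a parse error naming the column", {
  r <- make_record(stress_raw = "panicked")
  expect_error(derive_covariates(r), "stress_raw.*panicked")
})

test_that("the exclusion cascade counts sequentially and reconciles", {
  cfg <- sim_config(n_respondents = 2208, gender_other_rate = 59 / 2208,
                    outlier_rate_heightweight = 24 / 2208,
                    missing_rate_required = 292 / 2208, seed = 5)
  ex <- apply_exclusions(generate_cohort(cfg))
  a <- ex$audit
  expect_equal(a$n_heightweight_outliers, 24L)
  expect_equal(a$n_gender_other_or_unsure, 59L)
  expect_equal(a$n_missing_required, 292L)
  expect_equal(a$n_final, 1833L)
  expect_equal(nrow(ex$records), 1833L)
  expect_equal(a$n_final, a$n_input - a$n_heightweight_outliers -
                 a$n_gender_other_or_unsure - a$n_missing_required)
  # every excluded record has exactly one (first-rule) reason
  expect_equal(length(a$per_record_reasons), a$n_input - a$n_final)
  expect_setequal(names(a$per_record_reasons),
                  setdiff(generate_cohort(cfg)$respondent_id,
                          ex$records$respondent_id))
})

test_that("a clean cohort passes through untouched", {
  cfg <- sim_config(n_respondents = 150, gender_other_rate = 0,
                    outlier_rate_heightweight = 0, missing_rate_required = 0,
                    seed = 2)
  ex <- apply_exclusions(generate_cohort(cfg))
  expect_equal(ex$audit$n_final, 150L)
  expect_equal(ex$audit$n_heightweight_outliers, 0L)
  expect_equal(length(ex$audit$per_record_reasons), 0L)
})

test_that("exclusions match an independent brute-force filter", {
  cfg <- sim_config(n_respondents = 500, seed = 7,
                    missing_rate_required = 0.05)
  co <- generate_cohort(cfg)
  ex <- apply_exclusions(co)
  oracle <- oracle_exclusions(co, default_required_vars())
  expect_equal(ex$records$respondent_id, oracle$respondent_id)
})

test_that("filters 2 and 3 are idempotent on the cascade's own output", {
  cfg <- sim_config(n_respondents = 400, seed = 21,
                    missing_rate_required = 0.05)
  ex <- apply_exclusions(generate_cohort(cfg))
  again <- apply_exclusions(ex$records)
  expect_equal(again$audit$n_gender_other_or_unsure, 0L)
  expect_equal(again$audit$n_missing_required, 0L)
})

test_that("exclusion preconditions are enforced", {
  co <- generate_cohort(sim_config(n_respondents = 10, seed = 3))
  expect_error(apply_exclusions(co[0, ]), "empty")
  expect_error(apply_exclusions(co, required_vars = "nonexistent_var"),
               "not present")
})

test_that("cohorts round-trip through CSV with their configuration", {
  cfg <- sim_config(n_respondents = 40, seed = 14)
  co <- generate_cohort(cfg)
  path <- file.path(tempdir(), "cohort.csv")
  write_cohort(co, path, cfg)
  back <- read_cohort(path)
  expect_equal(nrow(back), 40L)
  expect_equal(back$gender_raw, co$gender_raw)
  expect_equal(back$mhc_3, co$mhc_3)
  cfg_echo <- jsonlite::read_json(paste0(path, ".config.json"))
  expect_equal(cfg_echo$seed, 14L)
  unlink(c(path, paste0(path, ".config.json")))
})
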