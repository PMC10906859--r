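test_that("2x2 odds ratios reproduce the published univariate contrasts", {
  # girls: troubled vs complete, and vulnerable vs complete
  expect_equal(round_half_up(odds_ratio_2x2(190, 65, 244, 419)$or, 2), 5.02)
  expect_equal(round_half_up(odds_ratio_2x2(463, 407, 244, 419)$or, 2), 1.95)
  expect_equal(odds_ratio_2x2(7, 7, 7, 7)$or, 1.0)
  expect_error(odds_ratio_2x2(0, 5, 3, 4), "zero cell")
  h <- odds_ratio_2x2(0, 5, 3, 4, haldane = TRUE)
  expect_true(h$or > 0 && h$ci_lower < h$or && h$or < h$ci_upper)
})

test_that("univariate logistic OR equals the 2x2 closed form", {
  set.seed(91)
  for (i in 1:60) {
    tab <- random_2x2(60)
    d <- expand_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    fit <- tryCatch(fit_logistic(case ~ exposed, d), error = function(e) NULL)
    if (is.null(fit)) next
    cf <- odds_ratio_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    expect_equal(fit$terms$or, cf$or, tolerance = 1e-6)
    # Wald CI from the fit equals the Woolf interval
    expect_equal(fit$terms$ci_lower, cf$ci_lower, tolerance = 1e-6)
    expect_equal(fit$terms$ci_upper, cf$ci_upper, tolerance = 1e-6)
  }
})

test_that("logistic fit contracts: separation, single class, tiny n", {
  sep <- data.frame(y = c(rep(0, 20), rep(1, 20)),
                    x = c(rnorm(20, -4), rnorm(20, 4)))
  expect_error(fit_logistic(y ~ x, sep), "separation")
  expect_error(fit_logistic(y ~ x, data.frame(y = rep(1, 10), x = rnorm(10))),
               "single class")
})

test_that("parameter recovery from a known multivariable logistic model", {
  beta <- c(girl = 0.63, stressed = 0.80)
  for (seed in 1:10) {
    set.seed(1000 + seed)
    d <- simulate_logistic_cohort(5000, beta, intercept = -1)
    fit <- fit_logistic(y ~ girl + stressed, d)
    expect_lt(abs(fit$terms$estimate[fit$terms$term == "girl"] - 0.63), 0.15)
    expect_lt(abs(fit$terms$estimate[fit$terms$term == "stressed"] - 0.80), 0.15)
  }
})

test_that("Wald 95% CI coverage sits in the nominal band", {
  set.seed(4242)
  true_or <- exp(0.7)
  hits <- 0L
  for (i in 1:500) {
    d <- simulate_logistic_cohort(400, c(x = 0.7), intercept = -0.5)
    fit <- fit_logistic(y ~ x, d)
    t1 <- fit$terms
    if (t1$ci_lower <= true_or && true_or <= t1$ci_upper) hits <- hits + 1L
  }
  expect_gte(hits / 500, 0.93)
  expect_lte(hits / 500, 0.97)
})

test_that("Nagelkerke R2 formula, bounds and monotonicity", {
  expect_equal(nagelkerke_r2(-50, -50, 100), 0)
  expect_equal(nagelkerke_r2(-50, 0, 100), 1)   # perfect prediction
  # hand-fit small dataset: formulas evaluated directly
  d <- data.frame(y = c(0, 0, 0, 1, 0, 1, 1, 1), x = c(1, 2, 3, 4, 5, 6, 7, 8))
  fit <- fit_logistic(y ~ x, d)
  r2_cs <- 1 - exp(2 * (fit$loglik_null - fit$loglik_model) / 8)
  expect_equal(fit$nagelkerke_r2, r2_cs / (1 - exp(2 * fit$loglik_null / 8)),
               tolerance = 1e-12)
  expect_error(nagelkerke_r2(-10, -12, 50), "worse than null")
  # monotone in the model log-likelihood
  lls <- seq(-40, -10, by = 5)
  r2s <- vapply(lls, function(l1) nagelkerke_r2(-45, l1, 60), numeric(1))
  expect_true(all(diff(r2s) > 0))
})

test_that("Hosmer-Lemeshow matches brute-force decile binning", {
  set.seed(92)
  d <- simulate_logistic_cohort(200, c(x = 1.2), intercept = -0.3)
  d$x <- d$x + runif(200, 0, 0.2)           # continuous spread of fitted probs
  fit <- fit_logistic(y ~ x, d, hosmer_lemeshow = TRUE)
  hl <- fit$hosmer_lemeshow
  expect_equal(hl$df, 8L)
  expect_equal(hl$statistic,
               oracle_hl_stat(fit$fitted, fit$y, g = 10), tolerance = 1e-10)
  # perfectly calibrated probabilities give statistic 0
  p <- rep(c(0.2, 0.4, 0.6, 0.8), each = 40)
  y <- unlist(lapply(c(0.2, 0.4, 0.6, 0.8),
                     function(q) rep(c(1, 0), round(c(q, 1 - q) * 40))))
  expect_lt(hosmer_lemeshow(p, y, g = 4)$statistic, 1e-20)
  expect_error(hosmer_lemeshow(c(0.2, 1.2), c(0, 1)), "strictly in")
})

test_that("VIF screen matches an independent least-squares solve", {
  set.seed(93)
  z <- rnorm(200)
  x <- cbind(a = z + rnorm(200, sd = 0.8), b = z + rnorm(200, sd = 0.8),
             c = rnorm(200))
  v <- vif_screen(x)
  for (j in 1:3) {
    r2 <- summary(lm(x[, j] ~ x[, -j]))$r.squared
    expect_equal(unname(v$vif[j]), 1 / (1 - r2), tolerance = 1e-8)
  }
  expect_false(v$flagged)
  # orthogonal design: VIFs 1
  o <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(unname(vif_screen(o)$vif), c(1, 1), tolerance = 1e-12)
  expect_error(vif_screen(cbind(a = z, b = z)), "collinear")
  expect_error(vif_screen(cbind(a = z, b = rep(1, 200))), "constant")
})

test_that("VIF agrees with the car implementation on a fitted model", {
  skip_if_not_installed("car")
  set.seed(94)
  d <- data.frame(x1 = rnorm(300), x2 = rnorm(300))
  d$x3 <- 0.6 * d$x1 + rnorm(300)
  ours <- vif_screen(d[, c("x1", "x2", "x3")])$vif
  theirs <- car::vif(lm(rnorm(300) ~ x1 + x2 + x3, d))
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-8)
})

test_that("Bonferroni threshold arithmetic and display convention", {
  expect_equal(bonferroni_threshold(0.05, 37), 0.05 / 37)
  expect_equal(round_half_up(bonferroni_threshold(0.05, 37), 4), 0.0014)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_error(bonferroni_threshold(0.05, 0), "positive integer")
})
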