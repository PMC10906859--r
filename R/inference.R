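# Logistic-regression modelling of status-group membership and diagnostics.

#' Odds ratio from a 2x2 table with Woolf confidence interval
#'
#' `OR = (a*d)/(b*c)` with `a` = exposed cases, `b` = exposed controls,
#' `c` = unexposed cases, `d` = unexposed controls, and the Woolf interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`.
#'
#' @param exposed_case,exposed_control,unexposed_case,unexposed_control
#'   non-negative cell counts.
#' @param conf_level confidence level (default 0.95).
#' @param haldane if `TRUE`, adds 0.5 to every cell (Haldane-Anscombe
#'   correction), permitting zero cells.
#' @return List with `or`, `ci_lower`, `ci_upper`, `log_or`, `se_log_or`,
#'   `p_value` (Wald).
#' @examples
#' odds_ratio_2x2(190, 65, 244, 419)$or  # ~5.02
#' @export
odds_ratio_2x2 <- function(exposed_case, exposed_control,
                           unexposed_case, unexposed_control,
                           conf_level = 0.95, haldane = FALSE) {
  cells <- c(exposed_case, exposed_control, unexposed_case, unexposed_control)
  if (any(!is.finite(cells)) || any(cells < 0))
    stop("cell counts must be non-negative")
  if (any(cells == 0)) {
    if (!haldane)
      stop("zero cell count: the closed-form OR is undefined; ",
           "set haldane = TRUE for the +0.5 correction")
    cells <- cells + 0.5
  }
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
  log_or <- log(a * d / (b * cc))
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  list(or = exp(log_or),
       ci_lower = exp(log_or - z * se), ci_upper = exp(log_or + z * se),
       log_or = log_or, se_log_or = se,
       p_value = 2 * stats::pnorm(-abs(log_or / se)))
}

#' Nagelkerke pseudo R-squared
#'
#' Cox-Snell `R2 = 1 - exp(2*(L0 - L1)/n)` rescaled by its attainable
#' maximum `1 - exp(2*L0/n)`, so a model no better than the null scores 0
#' and a perfectly predicting model scores 1.
#'
#' @param L0_ll null-model log-likelihood.
#' @param L1_ll fitted-model log-likelihood (must be `>= L0_ll` within
#'   tolerance).
#' @param n number of observations.
#' @return Scalar in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(L0_ll, L1_ll, n) {
  if (n < 1) stop("n must be at least 1")
  if (L1_ll < L0_ll - 1e-8)
    stop("model log-likelihood below null log-likelihood: fit worse than null")
  r2_cs <- 1 - exp(2 * (L0_ll - L1_ll) / n)
  max_cs <- 1 - exp(2 * L0_ll / n)
  if (max_cs <= 0) return(0)
  min(1, max(0, r2_cs / max_cs))
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Sorts observations by fitted probability into `g` near-equal groups
#' (quantile bin boundaries; ties on the fitted value are never split
#' across bins), then computes `X2 = sum over bins and outcome classes of
#' (O - E)^2 / E` with `g - 2` degrees of freedom.
#'
#' @param fitted_probs fitted probabilities in (0, 1).
#' @param observed 0/1 (or logical) outcomes.
#' @param g number of groups (default 10 "deciles of risk").
#' @return List of class `hosmer_lemeshow` with `statistic`, `df`,
#'   `p_value`, `g`, and a per-bin `table`.
#' @export
hosmer_lemeshow <- function(fitted_probs, observed, g = 10L) {
  observed <- as.numeric(observed)
  if (length(fitted_probs) != length(observed)) stop("length mismatch")
  if (any(is.na(fitted_probs)) || any(fitted_probs <= 0) || any(fitted_probs >= 1))
    stop("fitted probabilities must lie strictly in (0, 1)")
  if (!all(observed %in% c(0, 1))) stop("observed must be binary")
  if (g < 3L) stop("need at least 3 groups")
  n <- length(observed)
  if (n < 2L * g) stop("need at least 2 observations per group")

  br <- unique(stats::quantile(fitted_probs, probs = seq(0, 1, length.out = g + 1),
                               type = 7, names = FALSE))
  bin <- cut(fitted_probs, breaks = br, include.lowest = TRUE)
  obs1 <- tapply(observed, bin, sum)
  exp1 <- tapply(fitted_probs, bin, sum)
  nk <- tapply(observed, bin, length)
  keep <- !is.na(nk)
  obs1 <- obs1[keep]; exp1 <- exp1[keep]; nk <- nk[keep]
  exp0 <- nk - exp1
  if (any(exp1 == 0) || any(exp0 == 0))
    stop("degenerate binning: a group has expected count 0")
  stat <- sum((obs1 - exp1)^2 / exp1 + ((nk - obs1) - exp0)^2 / exp0)
  df <- g - 2L
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 g = g,
                 table = data.frame(n = as.integer(nk), observed = as.integer(obs1),
                                    expected = as.numeric(exp1))),
            class = "hosmer_lemeshow")
}

#' Variance inflation factor collinearity screen
#'
#' For each predictor column, `VIF_j = 1 / (1 - R2_j)` where `R2_j` is
#' from the least-squares regression of that column on all the others
#' (with intercept). Flags the design when the maximum VIF reaches 10.
#'
#' @param design numeric matrix or data frame of numerically coded
#'   predictors (at least two non-constant columns).
#' @return List of class `collinearity_screen` with `vif` (named vector),
#'   `max_vif`, `flagged`.
#' @export
vif_screen <- function(design) {
  x <- as.matrix(design)
  if (ncol(x) < 2L) stop("VIF screen needs at least 2 predictors")
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  const <- apply(x, 2, function(col) stats::sd(col) == 0)
  if (any(const)) stop("constant predictor: ", colnames(x)[which(const)[1L]])
  vif <- vapply(seq_len(ncol(x)), function(j) {
    fit <- stats::lm.fit(cbind(1, x[, -j, drop = FALSE]), x[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((x[, j] - mean(x[, j]))^2)
    if (r2 > 1 - 1e-12)
      stop("predictor '", colnames(x)[j], "' is perfectly collinear with the others")
    1 / (1 - r2)
  }, numeric(1))
  names(vif) <- colnames(x)
  structure(list(vif = vif, max_vif = max(vif), flagged = max(vif) >= 10),
            class = "collinearity_screen")
}

#' Binary logistic regression with odds ratios and diagnostics
#'
#' Maximum-likelihood logistic regression (via `stats::glm`, binomial
#' logit) of a binary outcome on categorical and/or continuous
#' predictors, reported the way epidemiological tables print it: per-term
#' odds ratios with Wald 95% confidence intervals and p-values,
#' Nagelkerke pseudo R-squared, and (for multivariable fits) the
#' Hosmer-Lemeshow calibration test. Complete-case on the model
#' variables. Perfect separation is detected from diverging coefficients
#' and raised as an error.
#'
#' @param formula model formula, outcome on the left (logical, 0/1, or a
#'   two-level factor whose second level is the event).
#' @param data data frame.
#' @param conf_level confidence level for the Wald intervals.
#' @param hosmer_lemeshow compute the HL test (default: only when the
#'   model has more than one predictor term).
#' @param hl_groups number of HL groups (default 10).
#' @return Object of class `logistic_fit`: list with `terms` (data frame
#'   of coefficient, SE, OR, CI bounds, p per non-intercept term),
#'   `n_used`, `loglik_null`, `loglik_model`, `nagelkerke_r2`,
#'   `hosmer_lemeshow` (or `NULL`), `glm` (the underlying fit),
#'   `outcome_levels`. Methods: `print`, `summary`, `coef`, `predict`.
#' @examples
#' d <- expand_2x2(190, 65, 244, 419)   # troubled-vs-complete by gender
#' fit_logistic(case ~ exposed, d)      # OR ~5.02
#' @export
fit_logistic <- function(formula, data, conf_level = 0.95,
                         hosmer_lemeshow = NULL, hl_groups = 10L) {
  mf <- stats::model.frame(formula, data, na.action = stats::na.omit)
  y <- stats::model.response(mf)
  if (is.factor(y)) {
    if (nlevels(droplevels(y)) != 2L) stop("outcome must have exactly two levels")
    y <- as.integer(y == levels(droplevels(y))[2L])
  } else y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("outcome must be binary")
  if (length(unique(y)) < 2L) stop("outcome has a single class; cannot fit")
  n <- length(y)
  X <- stats::model.matrix(attr(mf, "terms"), mf)
  if (n < ncol(X) + 1L) stop("too few complete cases for the number of parameters")

  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(),
                                         control = list(epsilon = 1e-12, maxit = 100)))
  cf <- fit$coefficients
  # polish with full Newton steps: IRLS stops on the deviance, which can
  # leave coefficients ~sqrt(epsilon) from the MLE on extreme tables
  for (it in 1:3) {
    polished <- tryCatch({
      mu <- stats::plogis(drop(X %*% cf))
      w <- pmax(mu * (1 - mu), 1e-12)
      cf + drop(chol2inv(chol(crossprod(X * sqrt(w)))) %*% crossprod(X, y - mu))
    }, error = function(e) NULL)
    if (is.null(polished) || any(!is.finite(polished))) break
    cf <- polished
  }
  fit$coefficients <- cf
  fit$fitted.values <- stats::plogis(drop(X %*% cf))
  fit$weights <- pmax(fit$fitted.values * (1 - fit$fitted.values), 1e-12)
  se <- sqrt(diag(chol2inv(chol(crossprod(X * sqrt(fit$weights))))))
  separated <- any(abs(cf[-1]) > 15) ||
    (all(fit$fitted.values[y == 1] > 1 - 1e-6) &&
       all(fit$fitted.values[y == 0] < 1e-6))
  if (separated)
    stop("perfect (or quasi-perfect) separation detected: ",
         "coefficient magnitudes diverge")

  ll1 <- sum(stats::dbinom(y, 1, fit$fitted.values, log = TRUE))
  p0 <- mean(y)
  ll0 <- sum(stats::dbinom(y, 1, p0, log = TRUE))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  keep <- names(cf) != "(Intercept)"
  terms_df <- data.frame(
    term = names(cf)[keep],
    estimate = unname(cf[keep]),
    std_error = unname(se[keep]),
    or = exp(unname(cf[keep])),
    ci_lower = exp(unname(cf[keep]) - z * unname(se[keep])),
    ci_upper = exp(unname(cf[keep]) + z * unname(se[keep])),
    p_value = 2 * stats::pnorm(-abs(unname(cf[keep]) / unname(se[keep]))),
    stringsAsFactors = FALSE)

  if (is.null(hosmer_lemeshow)) hosmer_lemeshow <- sum(keep) > 1L
  hl <- NULL
  if (isTRUE(hosmer_lemeshow)) {
    pr <- pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12)
    hl <- tryCatch(hosmer_lemeshow(pr, y, g = hl_groups), error = function(e) NULL)
  }

  structure(list(terms = terms_df, n_used = n,
                 loglik_null = ll0, loglik_model = ll1,
                 nagelkerke_r2 = nagelkerke_r2(ll0, ll1, n),
                 hosmer_lemeshow = hl,
                 coefficients = cf, fitted = fit$fitted.values,
                 y = y, formula = formula, conf_level = conf_level),
            class = "logistic_fit")
}

#' @export
print.logistic_fit <- function(x, digits = 2, ...) {
  cat("Binary logistic regression:", deparse(x$formula),
      sprintf("(n = %d)\n", x$n_used))
  t <- x$terms
  cat(sprintf("  %-28s OR %s (95%% CI %s-%s)  p = %s\n", t$term,
              formatC(t$or, digits = digits, format = "f"),
              formatC(t$ci_lower, digits = digits, format = "f"),
              formatC(t$ci_upper, digits = digits, format = "f"),
              format_pvalue(t$p_value)), sep = "")
  cat(sprintf("  Nagelkerke R2 = %.2f\n", x$nagelkerke_r2))
  if (!is.null(x$hosmer_lemeshow))
    cat(sprintf("  Hosmer-Lemeshow: X2 = %.2f (df %d), p = %s\n",
                x$hosmer_lemeshow$statistic, x$hosmer_lemeshow$df,
                format_pvalue(x$hosmer_lemeshow$p_value)))
  invisible(x)
}

#' @export
summary.logistic_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  log-likelihood: null %.3f, model %.3f\n",
              object$loglik_null, object$loglik_model))
  invisible(object)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

#' @export
predict.logistic_fit <- function(object, newdata = NULL,
                                 type = c("response", "link"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) {
    eta <- stats::qlogis(object$fitted)
  } else {
    tt <- stats::delete.response(stats::terms(object$formula))
    X <- stats::model.matrix(tt, stats::model.frame(tt, newdata,
                                                   na.action = stats::na.pass))
    eta <- drop(X %*% object$coefficients)
  }
  if (type == "link") eta else stats::plogis(eta)
}

#' Simulate a cohort from a known logistic model
#'
#' Draws binary covariates and a Bernoulli outcome from a specified
#' logistic model. Used for parameter-recovery and confidence-interval
#' coverage checks of [fit_logistic()].
#'
#' @param n number of observations.
#' @param beta named vector of true log-odds coefficients (names become
#'   columns; each covariate is Bernoulli(0.5) unless `prevalence` names
#'   it).
#' @param intercept true intercept on the log-odds scale.
#' @param prevalence optional named vector of covariate prevalences.
#' @return Data frame with the covariates and logical outcome `y`.
#' @export
simulate_logistic_cohort <- function(n, beta, intercept = -1,
                                     prevalence = NULL) {
  if (is.null(names(beta)) || any(names(beta) == ""))
    stop("beta must be a named vector")
  X <- sapply(names(beta), function(nm) {
    p <- if (!is.null(prevalence) && nm %in% names(prevalence)) prevalence[[nm]] else 0.5
    stats::rbinom(n, 1, p)
  })
  X <- matrix(X, nrow = n, dimnames = list(NULL, names(beta)))
  eta <- intercept + drop(X %*% beta)
  d <- as.data.frame(X)
  d$y <- stats::runif(n) < stats::plogis(eta)
  d
}

#' Expand a 2x2 exposure-outcome table to respondent-level rows
#'
#' Convenience for re-running a logistic regression from published cell
#' counts: returns a data frame with one row per respondent, a logical
#' `case` outcome and a 0/1 `exposed` indicator.
#'
#' @param exposed_case,exposed_control,unexposed_case,unexposed_control
#'   cell counts.
#' @return Data frame with `case` and `exposed`.
#' @export
expand_2x2 <- function(exposed_case, exposed_control,
                       unexposed_case, unexposed_control) {
  data.frame(
    case = rep(c(TRUE, FALSE, TRUE, FALSE),
               c(exposed_case, exposed_control, unexposed_case, unexposed_control)),
    exposed = rep(c(1, 1, 0, 0),
                  c(exposed_case, exposed_control, unexposed_case, unexposed_control)))
}

#' @export
print.hosmer_lemeshow <- function(x, ...) {
  cat(sprintf("Hosmer-Lemeshow: X2 = %.3f, df = %d, p = %s (g = %d)\n",
              x$statistic, x$df, format_pvalue(x$p_value), x$g))
  invisible(x)
}

#' @export
print.collinearity_screen <- function(x, ...) {
  cat("VIF screen (flag at 10):", if (x$flagged) "FLAGGED" else "ok", "\n")
  print(round(x$vif, 3))
  invisible(x)
}
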