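---
title: "Dual-factor mental health classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-factor mental health classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualfactor)
```

## The dual-factor model

The dual-factor conception of mental health treats mental *well-being*
and mental health *problems* as two correlated but distinct continua
rather than opposite ends of one axis. Crossing a dichotomised
well-being band with a dichotomised problems band yields four status
groups:

|                          | no problems  | problems                      |
|--------------------------|--------------|-------------------------------|
| **flourishing**          | complete (C) | symptomatic but content (S)   |
| **moderate-to-low**      | vulnerable (V) | troubled (T)                |

The point of the crossing is the off-diagonal: V respondents would look
"healthy" to a problems-only screen despite low well-being, and S
respondents report problems yet flourish.

## Instrument scoring

**MHC-SF** (14 items, 0 "never" to 5 "every day"; total 0–70). Items
1–3 measure emotional well-being, items 4–14 positive (social +
psychological) functioning. The categorical diagnosis counts items in
the top band (4–5) and bottom band (0–1): *flourishing* needs at least
one emotional and at least six functioning items in the top band;
*languishing* the mirror image in the bottom band. Since each criterion
claims six of the eleven functioning items, the diagnoses cannot
co-occur. For classification, `languishing` and `moderate` collapse
into `moderate_to_low`.

*Missing items.* `score_mhcsf()` defaults to a tolerant rule: band
counts are taken over answered items, so an unanswered item supports
neither diagnosis and incomplete responders drift toward `moderate`.
This is deliberate — dual-factor classification has to cover
respondents with a handful of skipped items, and the tolerant rule is
conservative about extreme diagnoses. The `total` score, by contrast,
requires all 14 answers. A `strict` complete-case mode is available.

**SDQ** (25 items, 0–2). Five subscales of five items; the total
difficulties score sums four of them (prosocial excluded; range 0–40)
after reverse-scoring the five positively worded difficulty items
(positions 7, 11, 14, 21, 25 of the standard published form) as
`2 - raw`. The instrument text leaves no way to compute caseness
without fixing this scoring sheet, so the package pins the standard
one. Caseness is `total >= 20`, the 90th percentile of a UK population
norm — the customary cutoff where no local norms exist, and
configurable (`sdq_cutoff`). The default missing-item policy is
complete-case (any missing item voids its subscale and the total);
standard prorating (subscale mean × 5, rounded, when at least 3 of 5
answered) is available behind `prorate = TRUE`.

**CYRM-12** (12 items, 1–5; total 12–60) is a plain sum, missing if any
item is missing, matching the listwise handling of covariates.

Internal consistency is estimated by Cronbach's alpha,
$\alpha = \frac{k}{k-1}\left(1 - \frac{\sum_j s_j^2}{s_T^2}\right)$,
on complete-case rows with $n-1$ variances.

## Covariates and the exclusion cascade

`derive_covariates()` dichotomises the raw survey questions: birth
country (Sweden vs other), guardian unemployment or long-term
sick-leave (none vs at least one across both guardians), school level
(grades 7–9 vs 10–12), any failing grade, any truancy, and considerable
stress ("fairly much"/"very much" vs "no"/"to some extent"). Missing
raw values propagate; unknown category codes are a parse error naming
the column and value, never silently recoded.

`apply_exclusions()` removes, in order: (1) respondents whose height
*or* weight lies beyond the mean ± 2 sample SDs of the full input set —
a screen against joke responses; (2) respondents reporting another or
uncertain gender identity (the gender analyses are girl/boy contrasts);
(3) respondents missing any required variable (demographics, school
questions, stress, and all CYRM and SDQ items — but *not* MHC items or
the SSS ladder, whose missingness is tolerated downstream). Each
excluded record is audited once under the first rule that caught it,
and the audit reconciles exactly. Two interpretation choices are made
explicit rather than silently assumed: the 2-SD rule uses the sample
(n−1) SD — immaterial at cohort sizes — and is computed once on the
full input, so re-running the cascade on its own output can in
principle flag new extremes (filters 2 and 3 are idempotent; the audit
makes any such drift visible).

## Group statistics

Categorical variables are compared across the four groups with a
Pearson chi-squared test of independence, switching to Fisher's exact
test when any expected cell count drops below 5 (configurable).
Continuous variables use one-way ANOVA with Tukey–Kramer post-hoc
comparisons (unequal group sizes), after screening distribution shape
with the bias-adjusted Fisher–Pearson skewness and excess kurtosis
coefficients.

Effect sizes follow the conventions of the survey-analysis literature:

* Cohen's $h = |2\arcsin\sqrt{p_1} - 2\arcsin\sqrt{p_2}|$ for
  proportions;
* Cohen's $d = |\bar{x}_1-\bar{x}_2| \,/\, \sqrt{(s_1^2+s_2^2)/2}$ for
  means. The equal-weight root-mean-square denominator is the package
  default because it is the convention the group-comparison tables this
  package mirrors were computed under; the n-weighted pooled SD gives
  visibly different values from the same summary statistics.

Pairwise "column proportion" comparisons are implemented as
two-proportion z-tests with Bonferroni adjustment within each variable
— the convention of the major commercial survey packages, offered as an
interpretation since cross-table letters rarely document their test.

Family-wise error control uses the Bonferroni threshold
$\alpha / m$. By default $m$ is the number of tests a pipeline run
actually performs; it can be pinned (e.g. `m_tests = 37`) to match an
external analysis plan, in which case $0.05/37$ displays as $0.0014$.

## Logistic regression

Group membership is modelled with pairwise binary logistic regressions
of each status group against the complete-mental-health reference —
never a pooled multinomial model, so estimates stay comparable with the
published table layout. `fit_logistic()` is maximum likelihood (IRLS
with full-Newton polish steps), with Wald standard errors, per-term
odds ratios and 95% CIs. On a saturated 2×2 design the OR equals the
cross-product closed form and the Wald CI equals the Woolf interval —
both identities are property-tested. Perfect separation is detected
(diverging coefficients or an error-free split of the fitted
probabilities) and raised as an error rather than reported with
meaningless standard errors.

Reported alongside each fit:

* **Nagelkerke $R^2$**: Cox–Snell
  $R^2_{cs} = 1-\exp\!\big(\tfrac{2}{n}(\ell_0-\ell_1)\big)$ rescaled
  by its maximum $1-\exp(\tfrac{2}{n}\ell_0)$;
* **Hosmer–Lemeshow** calibration for multivariable fits: observations
  sorted into $g = 10$ near-equal groups by fitted probability
  (quantile boundaries, ties never split), $\chi^2$ over observed vs
  expected events and non-events, $df = g-2$;
* **VIF screen**: $1/(1-R^2_j)$ from regressing each predictor on the
  others, flagged at 10.

The multivariable model (vulnerable vs complete) is restricted to
respondents with complete SSS, mirroring how an SSS-adjusted model
shrinks to SSS responders under listwise deletion.

## The synthetic cohort generator

No respondent-level data ship with the package; `generate_cohort()`
exists so the whole pipeline is runnable and testable. It emulates:

* a bivariate-normal latent (well-being $W$, problems $P$) pair with
  correlation $\rho$ (default −0.55), shifted by gender and by
  configurable covariate effects (defaults: girls lower $W$, higher
  $P$; considerable stress, truancy and failing grades likewise);
* graded-response item generation: each item is its instrument's
  latent plus independent Gaussian noise, cut at fixed thresholds
  shared across the instrument's items;
* covariate marginals matching published descriptive frequencies for a
  Swedish secondary-school population;
* MCAR missingness on MHC items (per item) and the SSS ladder, and
  implausible height/weight records for the exclusion screen to catch.

**Calibration constants, not claims.** The per-instrument noise SDs
(1.15 / 2.40 / 1.95 for MHC/SDQ/CYRM) and thresholds were calibrated
once, in a pilot simulation at n = 8000, to land the instruments near
their published psychometrics: alphas ≈ 0.91 / 0.77 / 0.74, flourishing
≈ 39%, caseness ≈ 17%, MHC mean (SD) ≈ 42.8 (14.2), SDQ ≈ 13.4 (6.2),
and an observed MHC–SDQ Spearman correlation ≈ −0.50. A single shared
noise SD cannot do this: with item noise well below the latent SD,
inter-item correlations exceed 0.6 and alpha saturates near 0.95 for
every instrument. The default $\rho = -0.55$ is likewise a calibration
constant chosen so the *observed-scale* correlation lands near −0.50
after discretisation and noise attenuation.

**Exactness of the exclusion demo.** Injected exclusion features use
deterministic counts (`round(rate * n)`) over disjoint record sets, and
clean heights/weights are drawn from bounded uniform ranges whose
maximum deviation is $\sqrt{3}$ SDs — safely inside the empirical 2-SD
bound even after outlier contamination inflates the SD. A configured
cascade therefore reproduces its arithmetic exactly: 2208 records with
rates 24/2208, 59/2208 and 292/2208 retain exactly 1833, at any seed.
(A grade-dependent height trend was considered and dropped: a
deterministic trend widens the maximum deviation faster than the
overall SD, so the 2-SD screen would start flagging clean records; the
screen only needs plausible magnitudes.)

**What the generator does not emulate.** Covariates are independent
given gender (real stress × gender × truancy dependence is untested
territory); missingness is MCAR, while real skip patterns are surely
informative; item thresholds are shared within an instrument, so
item-level difficulty spread is absent; and prosocial SDQ items are
only weakly coupled to the problems latent. Passing tests on synthetic
cohorts therefore validate the *machinery* — scoring rules, cascade
arithmetic, test statistics, regression diagnostics — not any
substantive claim about real adolescents.

## Numerical choices

* Percentages round half-up (away from zero) at 1 decimal in displays;
  ORs and effect sizes at 2; p-values at 3 with a `<0.001` floor.
  Internal values are never rounded.
* Quantiles (medians, 10th/90th percentiles) use linear interpolation
  between order statistics (type 7), the R default.
* Logistic fits converge on a relative deviance change of 1e-12 (max
  100 iterations) plus up to three full Newton polish steps, tight
  enough that the 2×2 Wald/Woolf identity holds to 1e-6.
* Zero cells make the closed-form OR an error by default; the
  Haldane–Anscombe +0.5 correction is opt-in, never silent.
* Fisher's exact test triggers on any expected count < 5; 2×2 p-values
  equal the exhaustive sum of hypergeometric probabilities of tables as
  or more extreme.
* A constant sample makes skewness/kurtosis (and Spearman, and alpha)
  an explicit error, never a silent zero.

## Problem sizes used in validation

The shipped test-suite simulations use cohorts of 150–10,000
respondents, 10-seed parameter-recovery runs at n = 5000, and a
500-replicate CI-coverage study at n = 400 — sizes at which binomial
sampling bounds make the assertions sharp while the full suite stays
fast. `scripts/acceptance.R` recomputes the package's headline numbers
from published table counts and a 2208-record synthetic cascade.

## Known limitations

* The SDQ item-to-subscale map and reverse-scored set are pinned to the
  standard self-report form; surveys with re-ordered items must supply
  responses in standard order (the codebook in `inst/extdata/` states
  it).
* Band counting for MHC missingness is a policy, not an instrument
  standard; both policies ship, and cohorts with heavy MHC missingness
  will see policy-sensitive group sizes.
* No imputation anywhere: the pipeline is listwise by design.
* The exclusion screen's 2-SD rule is distribution-naive; on raw data
  with genuinely heavy-tailed anthropometrics it will flag more than
  joke responses.
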