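# dualfactor

Dual-factor mental health classification and analysis for adolescent
survey data.

## What problem this addresses

Mental well-being and mental health problems are two correlated but
distinct continua, not opposite ends of one scale. School-survey
analyses that screen only for problems miss the *vulnerable* group —
adolescents with no clinical-range problems but low well-being — and
mislabel the *symptomatic but content*. The dual-factor model crosses a
well-being band with a problems band into four status groups:

|                     | no problems    | problems                    |
|---------------------|----------------|-----------------------------|
| **flourishing**     | complete (C)   | symptomatic but content (S) |
| **moderate-to-low** | vulnerable (V) | troubled (T)                |

`dualfactor` implements the full pipeline for epidemiologists and
school-health researchers working with item-level survey tables:

* **Instrument scoring** — MHC-SF (14 items, 0–70; categorical
  flourishing/languishing diagnosis by top/bottom frequency-band
  counts), SDQ (25 items; total difficulties 0–40 with standard
  reverse-scoring; caseness at total ≥ 20), CYRM-12 resilience totals,
  Cronbach's alpha.
* **Dual-factor classification** of every respondent, with audited
  handling of unclassifiable records.
* **Exclusion cascade** — implausible height/weight (mean ± 2 SD),
  non-binary/uncertain gender (for girl/boy contrasts), missing
  required variables — with a reconciled audit trail.
* **Group statistics** — chi-squared / Fisher exact omnibus tests,
  one-way ANOVA with Tukey–Kramer post-hocs, Cohen's
  *h* = |2·arcsin√p₁ − 2·arcsin√p₂|, Cohen's
  *d* = |m₁ − m₂| / √((s₁² + s₂²)/2), adjusted skewness/kurtosis,
  Spearman correlation, Bonferroni control.
* **Logistic regression** of each status group vs the complete-health
  reference: odds ratios with Wald/Woolf 95% CIs, Nagelkerke R²,
  Hosmer–Lemeshow calibration, VIF collinearity screen, separation
  detection.
* **Synthetic cohorts** — a Gaussian-copula generator
  (latent well-being/problems correlation, default −0.55) calibrated to
  realistic instrument psychometrics, so everything above runs and is
  tested without access to raw survey data.

## Worked example

```r
library(dualfactor)

cfg    <- sim_config(n_respondents = 2208, seed = 7)
cohort <- generate_cohort(cfg)
rpt    <- run_pipeline(cohort, m_tests = 37)
print(rpt)
```

```
== Dual-factor mental health analysis ==
Exclusion cascade:
  input                       2208
  - height/weight outliers      24
  - gender other/unsure         60
  - missing required             0
  = final                     2124
Dual-factor mental health status (n classified = 2124)
  complete                 (C)  n =  768  (36.2%)
  symptomatic_but_content  (S)  n =   41  (1.9%)
  vulnerable               (V)  n =  992  (46.7%)
  troubled                 (T)  n =  323  (15.2%)
  well-being x problems independence: X2 = 134.04, p = <0.001
MHC-SDQ Spearman correlation: -0.47
Bonferroni threshold: alpha/37 = 0.0014
Group differences significant at the corrected threshold:
   gender, grade_f, stressed, resilience_score, sss
Adjusted vulnerable-vs-complete model:
  ...
  stressed_x                   OR 1.72 (95% CI 1.36-2.17)  p = <0.001
  resilience_score             OR 0.87 (95% CI 0.86-0.89)  p = <0.001
  sss                          OR 0.75 (95% CI 0.70-0.80)  p = <0.001
  Nagelkerke R2 = 0.26
  Hosmer-Lemeshow: X2 = 7.34 (df 8), p = 0.501
```

Reading this: the synthetic cohort of 2,208 loses 84 records to the
screening cascade (no missing-required injection in the default
configuration); 46.7% of classified respondents land in the vulnerable
group; scored well-being and problems correlate at −0.47; and in the
adjusted model each additional resilience point multiplies the odds of
vulnerable (vs complete) status by 0.87, each SSS ladder step by 0.75,
with the model well calibrated (Hosmer–Lemeshow p = 0.50).

Single quantities work the same way from published cell counts:

```r
fit_logistic(case ~ exposed, expand_2x2(190, 65, 244, 419))$terms$or
#> 5.019552                  # girls, troubled vs complete
cohens_h(190/255, 244/663)
#> 0.7792279
```

A thin CLI over the same functions lives in `inst/cli/dualfactor.R`
(`simulate`, `score`, `classify`, `report` subcommands).

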