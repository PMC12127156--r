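# dietscores

Dietary inflammation and oxidative-balance scoring with survey-weighted
models of female reproductive health.

`dietscores` is for epidemiologists analysing 24-hour dietary recall data
from complex surveys (NHANES-style) who want to study how the inflammatory
and oxidative potential of diet relates to infertility and sex hormones,
and how much of that relationship runs through adiposity. It implements
the full chain as tested, reusable functions:

* **DII** — Dietary Inflammatory Index from a 26-component reference table:
  per nutrient, `z = (intake − μ_global)/σ_global`, centered percentile
  `2Φ(z) − 1`, weighted by the literature inflammatory effect score,
  summed. Higher = more pro-inflammatory.
* **DOBS** — Dietary Oxidative Balance Score from 17 nutrients:
  anti-oxidants scored 1–3 by sample tertile, pro-oxidants inversely,
  alcohol categorically (nondrinker 3 / nonheavy 2 / heavy 1). Higher =
  more anti-oxidative. Joint DII&DOBS classes contrast pro-inflammatory &
  pro-oxidative diets with anti-inflammatory & anti-oxidative ones.
* **Cohort preparation** — ordered eligibility filters with an exclusion
  log, HOMA-IR, obesity (BMI ≥ 30) and high-WC (≥ 88 cm) classification,
  weighted-median dichotomization of hormones, covariate coding.
* **Survey-weighted statistics** — Hajek means with linearization SEs,
  weighted percentages, design-based group tests, "Table 1" builder;
  weighted logistic/linear regression with sandwich (or Taylor) variance;
  restricted cubic spline dose–response with tests of overall association
  and nonlinearity.
* **Mediation** — quasi-Bayesian counterfactual ACME/ADE/total-effect
  decomposition of diet-score effects on infertility (risk-difference
  scale) or SHBG through BMI or WC, with the proportion mediated.
* **Synthetic cohorts** — a generator with planted exposure→mediator→
  outcome paths (`a`, `b`, `c`) and a Monte-Carlo oracle for the true
  proportion mediated, so every estimator has a parameter-recovery test.

## Worked example

```r
library(dietscores)

# a synthetic survey of 2,000 women with known mediation structure:
# a = 0.8 kg/m2 BMI per diet-score SD, b = 0.08 logit per kg/m2, c = 0.15
co <- generate_cohort(cohort_config(n_participants = 2000, seed = 7))
df <- score_cohort(co$data)          # adds dii, dobs, tertiles, diet_class
design <- survey_design(df$survey_weight)

range(df$dii)
#> [1] -6.209226  6.108011
table(df$diet_class)
#>   pro_inflammatory_pro_oxidative anti_inflammatory_anti_oxidative
#>                              552                              465
#>                        composite
#>                              983

fit <- fit_weighted_glm(infertility ~ dii + age, df, design)
fit$coefficients[2, c("term", "or", "or_low", "or_high", "p_value")]
#>   term       or   or_low  or_high    p_value
#> 2  dii 1.081149 1.013079 1.153793 0.01869317

m <- mediate_effects("infertility", "diet_score", "bmi",
                     covariates = "age", data = df, design = design,
                     n_draws = 1000, seed = 11)
m
#> Mediation of diet_score -> infertility via bmi (risk_difference scale), n = 2000, 1000 draws
#>   acme            0.00787 [  0.00450,   0.01189]  p = 0
#>   ade             0.02558 [  0.00739,   0.04348]  p = 0.002
#>   total_effect    0.03345 [  0.01599,   0.05148]  p = 0
#>   % mediated       23.52%  [12.39%, 53.22%]

true_proportion_mediated(co)   # generating-model oracle for the same contrast
#> [1] 0.2991376
```

Read: a one-SD pro-inflammatory shift in the diet score raises the
infertility odds (OR per DII unit 1.08 here) and, per the counterfactual
decomposition, raises infertility risk by about 3.3 percentage points in
total, of which ~0.8 points (24%, CI 12–53% at this n) flow through BMI —
bracketing the generator's true 29.9%.

The whole surface — exclusion flowchart, weighted descriptive tables,
logistic/linear forest tables, RCS curves, mediation tables, run manifest —
comes from one call:

```r
res <- run_pipeline(list(
  cohort_config = list(n_participants = 2000, seed = 7),
  out_dir = "out", seed = 7))
```

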