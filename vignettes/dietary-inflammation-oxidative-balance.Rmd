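---
title: "Dietary inflammation, oxidative balance, and reproductive health: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary inflammation, oxidative balance, and reproductive health: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietscores)
```

## The scientific problem

Chronic low-grade inflammation and oxidative stress are plausible dietary
pathways to female infertility and disturbed sex-hormone regulation, and
adiposity sits on the causal path: diets that promote inflammation also
promote weight gain, and adiposity itself disturbs ovulation and lowers sex
hormone-binding globulin (SHBG). `dietscores` implements the full analysis
chain used to study these questions in cross-sectional nutrition surveys of
women of reproductive age: two composite diet-quality exposures (DII and
DOBS), survey-weighted descriptive statistics and regression, spline
dose-response, and a counterfactual mediation decomposition through BMI and
waist circumference (WC).

## The two diet scores

**Dietary Inflammatory Index (DII).** Each of 26 nutrients obtainable from a
24-hour recall has a literature-derived *global* daily mean intake
$\mu_j$, standard deviation $\sigma_j$, and an inflammatory effect score
$e_j$ (positive = pro-inflammatory). For participant $i$ with intake
$x_{ij}$:

$$z_{ij} = \frac{x_{ij} - \mu_j}{\sigma_j},\qquad
  \mathrm{DII}_i = \sum_j \left(2\,\Phi(z_{ij}) - 1\right) e_j .$$

The percentile transform is the standard normal CDF of the z-score: it is
the canonical construction, smooth, and independent of the analytic sample.
Published verbal descriptions are ambiguous about whether the effect score
multiplies the z-score before the percentile step or the centered percentile
after it; the bounded "−1 to 1" framing is only consistent with the latter,
which is our default. The other reading is available behind
`compute_dii(..., effect_in_z = TRUE)` without any claim about which
variant any particular study ran. Because $\Phi$ never reaches 0 or 1,
$|\mathrm{DII}| < \sum_j |e_j|$ strictly. Intakes are raw daily amounts;
total energy enters later as a model covariate rather than through
energy-standardized scoring.

**Dietary Oxidative Balance Score (DOBS).** Seventeen nutrients: 14
anti-oxidants scored 1–3 by ascending sample tertile, 3 pro-oxidants scored
inversely (4 − tertile), except alcohol, which is scored categorically —
nondrinker (0 g/day) = 3, nonheavy = 2, heavy = 1. We place the heavy
cutoff at 15 g/day, the women's threshold used in the oxidative-balance
literature; the source descriptions name the categories but not the gram
value. Tertile cutpoints are the 33⅓/66⅔ linear-interpolation quantiles of
the analytic sample, unweighted by default (a survey-weighted option
exists; which one underlies published cutpoints is usually unstated), with
ties going to the lower tertile — deterministic and order-independent. The
log transform flagged for vitamin C, beta-carotene, and B12 is applied as
`log1p` (zero intakes occur); it cannot change tertile membership — we keep
it for fidelity and for any future non-quantile scoring rule.

**Joint classes.** DII tertile 3 ∧ DOBS tertile 1 = pro-inflammatory &
pro-oxidative; DII tertile 1 ∧ DOBS tertile 3 = anti-inflammatory &
anti-oxidative; everyone else composite. The three classes partition the
cohort.

## Cohort preparation

Eligibility filters run in a fixed order — males, age outside 20–45 years,
missing any active diet component, missing any outcome or mediator
(infertility, SHBG, total testosterone, estradiol, BMI, WC) — and each
step's removals are logged so constructed fixtures can assert them.
Hormones are dichotomized at the survey-weighted median (the weights are
the backbone of every other estimate; an unweighted flag exists), with
values exactly at the median going low. Obesity is BMI ≥ 30 kg/m²; high-WC
is WC ≥ 88 cm, both boundary-inclusive. HOMA-IR = insulin (mU/L) × glucose
(mmol/L) / 22.5. PIR keeps its missing values as an explicit `miss`
category; physical activity splits at 600 MET-min/week, boundary in the
active group.

## Survey-weighted estimation

The default design treats observations as independently drawn with unequal
probabilities (`weights_only_robust`): means are Hajek ratio estimators with
linearization SEs, regression uses the weights as prior weights with HC0
sandwich covariance, and everything is invariant to rescaling the weights.
When stratum and PSU identifiers exist, a stratified between-PSU Taylor
linearization is available. We deliberately chose estimators that **reduce
exactly to their classical unweighted counterparts under equal weights**:
two-group comparisons use a weighted Welch-type t (Satterthwaite df), which
equals `t.test()` exactly at equal weights; categorical comparisons use a
Pearson chi-square on the weighted table rescaled to n with a first-order
Kish design-effect correction (deff = 1 exactly at equal weights). Logistic
fits use the quasi-binomial family so non-integer weighted responses are
accepted; coefficients are identical to binomial ML. Perfect separation is
flagged when any fitted probability sits within 1e-8 of the boundary.

## Restricted cubic splines

The spline basis is the natural-spline truncated-power construction
normalised by the squared boundary-knot span: linear tails, C² everywhere.
Default 4 knots at the 5th/35th/65th/95th weighted percentiles (3 and 5
knot variants use the conventional percentile sets); published analyses
rarely state knot placement, so reproducing any specific published curve is
not promised and knot settings are recorded in the output. `p_overall`
is a robust joint Wald test of all spline terms, `p_nonlinear` of the
nonlinear terms only; the curve grid reports log-odds differences centred
at the weighted-median exposure with delta-method pointwise intervals.

## Mediation

`mediate_effects()` implements the quasi-Bayesian counterfactual two-model
estimator: a weighted linear mediator model and a weighted outcome model
(logistic for infertility, linear for SHBG), robust covariances, parameter
vectors drawn from each model's asymptotic normal distribution, and
potential-outcome means simulated on the observed covariate distribution
(the mediator residual draw is shared between exposure arms, which lowers
Monte-Carlo variance without changing the estimand). Binary-outcome
effects are reported on the **risk-difference scale**, so the proportion
mediated ACME/(ACME+ADE) matches the "% of effect" framing directly; total
= ACME + ADE holds exactly, draw by draw. The exposure contrast defaults
to 0 → 1, i.e. one SD when the exposure is a standardized score; for the
joint diet classes we contrast anti/anti (1) against pro/pro (0). The
default 1,000 draws give proportion-mediated Monte-Carlo noise well under
a percentage point at the cohort sizes used here; the seed is a required
argument. When the total-effect interval covers zero the proportion
mediated is flagged unstable and its interval withheld — a ratio with a
near-zero denominator is noise. Exposure–mediator interactions and joint
multiple mediators are out of scope.

## The synthetic-cohort generator

`generate_cohort()` emulates the kind of survey sample these analyses run
on, with a *known* generating model so every stage has a parameter-recovery
oracle. A latent standardized diet score $d_i \sim N(0,1)$ drives:

* **intakes** — log-normal per component (positive and right-skewed, like
  real nutrient data), median at the component's global reference mean,
  log-scale SD 0.5, and a ±0.25 loading on $d_i$ signed by the component's
  inflammatory direction; alcohol is zero-inflated (half nondrinkers);
* **mediator** — BMI = 28 + a·d + N(0, 4.5) kg/m²; WC tracks BMI
  (slope 2.2, extra noise SD 6 cm);
* **outcome** — infertility ~ Bernoulli(logit⁻¹(α + c·d + b·BMI)), with
  α chosen so the default prevalence is 12.66%, the study-scale value;
  covariate effects on the outcome default to zero so the intercept
  calibration is exact;
* **SHBG** — linear Gaussian (intercept 62 nmol/L, −6 per score SD, −1.5
  per kg/m² BMI, residual SD 22); it can stray negative in the far tails —
  a deliberate price for exact linear-oracle tests;
* **survey weights** — i.i.d. shifted gamma with mean 1 (real multistage
  weight distributions are never published; any positive distribution
  exercises the weighted estimators), with optional balanced stratum/PSU
  blocks.

Default a = 0.8 kg/m² per SD, b = 0.08 logit per kg/m², c = 0.15 logit per
SD — adiposity effects of realistic epidemiological magnitude that put the
proportion mediated near 30%, comfortably inside the range where recovery
is informative. Each variable draws from its own deterministically derived
sub-stream, so adding a variable never perturbs existing draws, and
identical configs give byte-identical cohorts.
`true_proportion_mediated()` evaluates the generating model's
counterfactual means by Monte-Carlo on the risk-difference scale — the
oracle the mediation estimator is tested against.

What the generator does **not** emulate: multistage cluster sampling,
item-specific nonresponse beyond PIR, measurement error in recall data,
skewed/heteroskedastic hormone errors, or real nutrient-nutrient
correlation beyond the single latent factor. Passing recovery tests shows
the estimators are correct under the stated model, not that any real-data
finding is confirmed.

## Numerical choices and degenerate inputs

Tertiles with fewer than 3 finite values, or all values identical, are
errors, as are median splits of constant vectors; a component named in an
active score table but absent from the intake data is an error rather than
a silent zero. Weighted medians use the cumulative-weight convention whose
equal-weight even-n case returns the usual midpoint (values 1..4 → 2.5).
Wald inference uses normal quantiles (the cohorts of interest have
thousands of records). Single-PSU strata contribute zero variance in
Taylor mode. Problem sizes in the test and acceptance suites — 2,000 null
replicates of n = 500 for test-size calibration, 10,000 participants for
mediation recovery, 500 replicates for null ACME coverage — were chosen as
the smallest sizes at which the binomial/Monte-Carlo error of the check is
several times smaller than the tolerance being asserted.

## Pipeline

`run_pipeline()` chains the stages from one config (simulated or supplied
input): exclusion log, overall and obesity-stratified weighted descriptive
tables, logistic and linear exposure model tables, RCS p-values and curve
grids, and the mediation table, plus a JSON manifest (versions, seed,
settings) sufficient to reproduce the run. Every number in every artifact
is produced by one exported module function. Significance marking uses
two-sided p < 0.05 with no multiplicity correction, matching the reporting
convention of the analyses this package supports.

## Known limitations

The DII/DOBS reference tables are transcriptions of published constants,
not re-derivations; cross-sectional data cannot support causal claims and
the mediation decomposition assumes sequential ignorability; the
weights-only variance ignores clustering gains/losses unless PSU
identifiers are supplied; and hormone dichotomization at the median
discards dose information by design.
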