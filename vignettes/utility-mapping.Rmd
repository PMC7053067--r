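---
title: "Mapping PDQ-39 scores to EQ-5D-3L utilities: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping PDQ-39 scores to EQ-5D-3L utilities: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdqmap)
```

## The problem

Cost-utility analyses need utilities — preference weights for health
states anchored at 1.0 (full health) and 0.0 (death) — but many clinical
trials in Parkinson's disease (PD) collect only the disease-specific
PDQ-39 questionnaire, not a generic preference-based instrument such as
the EQ-5D-3L. When utilities were never measured, an accepted alternative
is *response mapping* (crosswalking): predict each EQ-5D-3L dimension's
response level from the PDQ-39 subscale profile with a pre-estimated
regression model, then value the predicted health state with a country
tariff. `pdqmap` implements that pipeline end to end for two-arm
longitudinal trials, together with the statistics used to compare mapped
utilities between treatment arms, and a synthetic trial generator so every
stage is testable without access to restricted patient-level data.

## Instruments and scoring

The PDQ-39 has 39 items in eight subscales (mobility 10 items, activities
of daily living 6, emotional well-being 6, stigma 4, social support 3,
cognitions 4, communication 3, bodily discomfort 3). Items are scored
0–4 ("never" … "always") and each subscale index is

$$\text{index} = 100 \times \frac{\sum \text{item scores}}{4 \times
  n_\text{items answered}},$$

a 0–100 scale with higher values meaning worse health-related quality of
life; the summary index (SI) is the mean of the eight. Following the
instrument's scoring convention, a subscale is scorable when at least half
its items are answered (scored over the answered items); an unscorable
subscale makes the whole profile incomplete. The identity
$\text{index} = 25 \times \overline{\text{item}}$ is used as an algebraic
test oracle. The pipeline equally accepts precomputed subscale indices,
since trial exports often provide those instead of item-level data; the
two granularities are mutually exclusive per dataset.

The EQ-5D-3L describes a health state as five dimensions (mobility,
self-care, usual activities, pain/discomfort, anxiety/depression) at three
levels (1 no problems, 2 some problems, 3 extreme problems).

## The two mapping families

Both families predict, for each EQ-5D dimension, a probability triple
$(\vartheta_1, \vartheta_2, \vartheta_3)$ over the three levels and then
assign the maximum-probability level.

**Ordinal (Cauchit link).** A cumulative model per dimension with
cut-points $\alpha_1 < \alpha_2$ and slopes $\beta$ over a declared subset
of the subscale indices:

$$\vartheta_1 = 0.5 - \tan^{-1}(-\alpha_1 + \beta'X)/\pi, \qquad
  \vartheta_1 + \vartheta_2 = 0.5 - \tan^{-1}(-\alpha_2 + \beta'X)/\pi,$$

with $\vartheta_3$ the complement. The Cauchit (inverse-Cauchy) link has
heavier tails than the logit, so extreme linear predictors still leave
non-negligible probability on the outer levels. $\alpha_1 < \alpha_2$ is
enforced at load time: it is exactly the condition for the middle
category's probability to be non-negative, and with non-negative slopes
the model is stochastically monotone — worsening any covered subscale
never raises the probability of "no problems" (property-tested).

**Multinomial logit.** Level 1 is the pivot outcome with linear score 0;
levels 2 and 3 have scores $s_\ell = \beta_\ell' x$ over an intercept, the
eight subscale indices, age (years) and a gender indicator (1 = female by
default; the coefficient file declares its coding and an optional
age-centering constant, and a coding mismatch is a load-time error). The
triple is the softmax $e^{s_\ell} / \sum_j e^{s_j}$, computed with
max-subtraction so scores of any magnitude cannot overflow.

**Level assignment.** The argmax of the triple, with exact ties broken
toward the lower (less severe) level — a deterministic, conservative
convention for an event that has measure zero with continuous covariates.
An independent enumeration oracle checks the argmax in the tests.

**Coefficients are inputs, not estimates.** The source publications'
regression coefficients are consumed from YAML files and are never
re-fitted here. Because those coefficient tables are not reproduced in
this package, the shipped `demo_ordinal.yaml` and `demo_multinomial.yaml`
are clearly-labelled *synthetic* demonstration sets: severity-increasing
round numbers whose cut-points and slopes were chosen so that typical
PDQ-39 profiles (SI roughly 20–50) spread across all three levels —
$\eta = \beta'X$ crosses $\alpha_1$ inside that range. Users who
transcribe published coefficient sets supply a file of the same shape;
the schema supports plain linear terms only (no interactions or
transformed covariates), which is a documented limitation. When
transcribing, confirm the source model's sign convention for $\beta'X$
against its publication; the formulas here take severity-increasing
predictors literally.

## Valuing states: the tariff engine

A value set converts a state into a utility additively:

$$u = 1
  - c_\text{any}\,[\text{any level} > 1]
  - \sum_d \delta_d(\ell_d)
  - c_\text{extreme}\,[\text{any level} = 3],$$

with $\delta_d(1) = 0$. This is the structure of the standard UK
time-trade-off tariff, which ships with the package
(`uk_tto.yaml`; its floor, state 33333, is $-0.594$). Value sets lacking a
term set it to zero. Load-time validation requires the full-health
constant to be exactly 1.0, non-negative decrements, and per-dimension
level-3 decrement ≥ level-2 decrement; together these guarantee monotone
dominance over the whole 243-state lattice, which the tests verify
exhaustively against an independent additive oracle. A synthetic
round-number value set (`test_valueset.yaml`) is used in tests so no
transcription is needed to build the package; other national tariffs
(e.g. the French value set used as an additional analysis in this
literature) are supplied by the user as YAML files of the same shape.
Utilities are kept at full floating precision; rounding is purely a
reporting concern.

## Trial statistics

The longitudinal comparison works on a subject × visit utility panel:

* **Complete cases.** A "case" is a subject; subjects missing any
  scheduled visit are excluded, with a per-arm report (percentages rounded
  to integers, so 4 of 127 reports 3% and 5 of 124 reports 4%). A
  per-visit alternative is available by configuration.
* **Change from baseline** per subject per follow-up visit; positive
  change in utilities is improvement.
* **Within-arm test**: one-sample two-tailed Student's t of mean change
  against 0 (equivalent to a paired t of visit vs baseline — the classical
  description does not distinguish, and this form is the one tested).
  **Between-arm test**: two-sample pooled-variance Student's t on change
  scores (Welch by option; pooled is the default because the classical
  analysis names Student's test). Both are implemented closed-form: the
  degenerate zero-variance case must return an exact verdict (mean 0 ⇒
  p = 1, else p = 0) rather than an error, and the implementation is
  checked against `stats::t.test` to 1e-10 as an independent oracle.
* **Bonferroni correction** over the three follow-up visits: per-test
  threshold $0.05/3 = 0.0167$ (reported as 0.017 at three decimals),
  adjusted p-values $\min(1, 3p)$; confidence intervals are produced at
  the adjusted level. Raw and adjusted p are both reported, so either
  reading of borderline results is reproducible.
* **Repeated-measures ANOVA**: classical univariate mixed two-way form
  (between factor arm, within factor visit, subjects nested in arm) via
  `stats::aov` with an `Error(subject)` stratum, baseline included as a
  visit. A Greenhouse–Geisser epsilon estimated from the pooled
  within-arm covariance is reported with corrected p-values for the
  within-subject effects, but the uncorrected tests are primary — the
  classical analysis this reproduces applies no sphericity correction.
* **Responsiveness**: effect size ES = mean change / SD(baseline), and
  standardized response mean SRM = mean change / SD(change), sample SDs,
  per arm and combined. Zero SDs yield `NA` with a degenerate flag, never
  a silent infinity.
* **Severity strata**: Tukey boxplot statistics (median, quartiles by
  linear interpolation — `stats::quantile` type 7, fixed because boxplot
  statistics depend on the convention — whiskers at 1.5 × IQR clipped to
  the data range, outliers listed) of utilities or the PDQ-39 SI per
  Hoehn & Yahr stage, pooling observations from all visits. Stages with
  fewer than 10 observations are flagged low-reliability rather than
  suppressed, echoing the caution that sparse late-stage strata support
  only weak conclusions.

## The synthetic trial generator

The generator emulates a DBS-vs-best-medical-therapy trial in PD with
early motor complications: 124 + 127 subjects, visits at 0/5/12/24
months, mean age 52 (SD 6), baseline H&Y at most 2.5, and an 8-point
between-arm SI effect — the headline PDQ-39 result of that literature.

The latent model is deliberately the simplest structure matching a
change-from-baseline analysis: subject random intercept plus
visit-specific arm means with Gaussian occasion noise. The intercept's
variance share equals `within_subject_corr` (default 0.6), both arms
start at `baseline_si_mean`, arm B stays flat, and arm A's latent mean
drops by the full `arm_effect_si` at every follow-up visit (mirroring the
early-and-sustained improvement pattern reported for stimulation). The
eight subscale values are exchangeable perturbations of the latent index
(independent noise, SD `subscale_spread_sd`) — no per-subscale effect
profile is modelled because none is reported. Missingness is at the
subject level (one randomly chosen follow-up visit withheld for a
`missing_case_rate` fraction of subjects, default 9/251 ≈ 3.6%), matching
complete-case semantics. H&Y stage is sampled at baseline, held fixed,
and shifts the subject's latent severity by `hy_si_slope` points per
stage (default 6, centred at the design's expected stage, with the
stage-driven variance carved out of the random-intercept share so the
total baseline SD is preserved); without such a coupling the
severity-stratified analysis would summarise pure noise. All randomness
flows from a single integer seed through a scoped generator
(`withr::with_seed`), so identical designs and seeds give byte-identical
output and the global RNG state is untouched.

**Numerical choices.** Subscales are clipped (not resampled) to
[0, 100]. Clipping is a bias source when the baseline sits near a
boundary, so the defaults were fixed from the closed-form mean of a
clipped normal: with `baseline_si_mean = 32`, `baseline_si_sd = 12` and
`subscale_spread_sd = 8`, truncation absorbs about 0.25 of the 8-point
effect (< 5%), and the generator *rejects* designs where it would absorb
more than half (an unusable scenario, e.g. a baseline mean of 3). The
500-replicate unbiasedness check in the test suite confirms the realised
effect. The baseline location/spread themselves are plausible placeholders
for this population — the source trial's subscale-level moments are not
public — and are stated once here rather than tuned.

The generator can also draw probabilistic ground-truth EQ-5D states from
any mapping model's predicted probabilities (a random draw per dimension,
not the argmax), which is how the deterministic predictor's behaviour is
exercised against a known data-generating process.

**What passing tests do and do not show.** The generator produces
Gaussian, exchangeable subscales with a single latent severity axis. Real
PDQ-39 data are skewed, bounded, multidimensional (subscales respond
differently to treatment), and missingness is rarely purely
subject-level. Tests passing on synthetic data therefore validate the
*pipeline's correctness and calibration* (type-I control, effect-direction
recovery, unbiased effect generation), not the clinical accuracy of any
particular coefficient set on real patients.

## Problem sizes used in the checks

The test suite and the acceptance script run: probability normalization
over 10,000 random covariate draws × 20 random models per family;
the exhaustive 243-state tariff lattice for both shipped value sets;
10,000 argmax triples including engineered ties; 100 random datasets for
t-oracle parity; 1000 zero-effect replicates at full study size for null
calibration (between-arm rejection at the 0.017 threshold stays below
2.5%); and 200 full-pipeline replicates per family for effect-direction
recovery. These sizes give Monte-Carlo error well inside the margins
being asserted while keeping a complete run in the order of a minute.

## Known limitations

* The shipped mapping coefficients are synthetic demonstrations; results
  with them are method demonstrations, not clinical estimates.
* Argmax level assignment concentrates predictions on modal states (many
  subjects map to 11111 at mild severity), which compresses utility
  variance relative to expected-utility mapping; the per-dimension
  probability table is retained in the output so expected-utility
  variants could be added, but none is computed here.
* The coefficient schema supports plain linear terms only.
* No multiple imputation: the complete-case approach matches the analysis
  being reproduced and is appropriate only when missingness is low.
* The repeated-measures ANOVA treats baseline as a visit; using baseline
  as a covariate (ANCOVA) is a reasonable alternative the classical
  description leaves unspecified.
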