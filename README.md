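# pdqmap

Predicting EQ-5D-3L utilities from PDQ-39 data in two-arm longitudinal
trials in Parkinson's disease (PD).

Many PD trials collect the disease-specific PDQ-39 questionnaire but not a
generic preference-based instrument, so the utilities needed for
cost-utility analysis were never measured. `pdqmap` implements the accepted
alternative — *response mapping* — as a reusable pipeline for
biostatisticians and health economists:

1. **Score** PDQ-39 item responses into the eight 0–100 subscale indices
   and the summary index (SI = mean of the eight; higher = worse).
2. **Map** each subscale profile to EQ-5D-3L dimension levels with either
   of two model families, taking coefficients from config files:
   * ordinal regression with Cauchit link, per dimension:
     `ϑ1 = 0.5 − atan(−α1 + β'X)/π`, `ϑ1 + ϑ2 = 0.5 − atan(−α2 + β'X)/π`;
   * multinomial logit with age and gender, level 1 the pivot outcome:
     `P(level ℓ) = exp(s_ℓ)/Σ_j exp(s_j)` with `s_1 = 0`;
   then assign the maximum-probability level per dimension (ties break
   toward the less severe level).
3. **Value** the predicted 5-digit health state with a country tariff
   (additive decrements from 1.0; the UK time-trade-off value set ships
   with the package).
4. **Analyse** the resulting utility panel: complete-case filtering with
   an exclusion report, within- and between-arm change-from-baseline
   Student's t-tests with Bonferroni correction (0.05/3 = 0.017),
   repeated-measures ANOVA, responsiveness statistics (ES, SRM), and
   Hoehn & Yahr severity-stratified boxplot summaries.

A synthetic trial generator with known ground truth (124 + 127 subjects,
visits at 0/5/12/24 months, an 8-point SI treatment effect, ~3–4%
incomplete cases) makes the whole pipeline testable without restricted
patient-level data. The shipped mapping coefficients are clearly-labelled
synthetic demonstration sets; users transcribe published coefficient
tables into the same YAML shape to run a real analysis.

## Worked example

The `analysis/` scripts run the full workflow; each step writes its
tables under `results/`:

```sh
Rscript analysis/01_simulate.R          # synthetic two-arm trial -> CSV
Rscript analysis/02_map_utilities.R     # score -> map -> tariff -> stats
Rscript analysis/03_trial_comparison.R  # longitudinal comparison tables
Rscript analysis/04_severity_strata.R   # H&Y-stratified distributions
```

Step 1 prints the simulated PDQ-39 summary index (arm A improves by ~8
points at follow-up, arm B stays flat):

```
Mean PDQ-39 summary index by arm and visit (points, higher = worse):
     0    5   12   24
A 32.1 24.3 23.8 26.1
B 30.7 31.9 31.2 32.2
```

Step 2 maps those profiles through both families and the UK tariff:

```
Mean predicted UK utility by arm and visit (ordinal family):
      0     5    12    24
A 0.837 0.924 0.934 0.903
B 0.837 0.842 0.843 0.821
```

Step 3 reproduces the trial comparison on the mapped utilities (ordinal
family shown): the stimulation-like arm improves significantly at every
follow-up visit, the medical-therapy arm at none, and the between-arm
difference favours arm A throughout at the 0.017 threshold —

```
Within-arm change from baseline (utility points):
 arm visit_month estimate      p  p_adj
   A           5    0.085 <0.001 <0.001
   B           5    0.002  0.895  1.000
   A          12    0.099 <0.001 <0.001
   B          12    0.008  0.647  1.000
   A          24    0.067 <0.001 <0.001
   B          24   -0.018  0.310  0.930

Between-arm difference in change (A - B), threshold 0.017:
 visit_month estimate    t  df      p
           5    0.083 3.56 242 <0.001
          12    0.091 3.72 242 <0.001
          24    0.085 3.43 242 <0.001

Repeated-measures ANOVA arm effect: F(1, 242) = 13.5, p <0.001
```

A between-arm utility difference of ~0.08 exceeds the commonly cited
minimal clinically important difference for EQ-5D-3L utilities
(0.09–0.10) at some visits and approaches it at others; step 4 shows
median predicted utility falling with H&Y stage (0.848 at stage 2.5 vs
1.000 at mild stages under the ordinal family), the face-validity pattern
expected of any sensible mapping.

The same machinery is available programmatically:

```r
library(pdqmap)
ext <- function(f) system.file("extdata", f, package = "pdqmap")
rec <- generate_trial(trial_design(seed = 1))
res <- run_pipeline(list(
  data = {p <- tempfile(fileext = ".csv"); write_trial_table(rec, p); p},
  family = "both",
  coefficients = list(ordinal = ext("demo_ordinal.yaml"),
                      multinomial = ext("demo_multinomial.yaml")),
  value_sets = list(ext("uk_tto.yaml"))))
res$ordinal.UK$stats$between   # per-visit between-arm tests
```

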