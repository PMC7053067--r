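# SYNTHETIC demonstration coefficient set for the multinomial-logit
# mapping family (level 1 = pivot outcome, linear score 0). These are NOT
# the published Kent et al. coefficients; they are severity-increasing
# round numbers producing plausible level mixes for typical PDQ-39
# profiles at ages around 50-60. Gender coding: indicator 1 = female.
# Unlisted covariates are zero.
family: multinomial
label: synthetic-demo-multinomial
gender_coding: {female: 1, male: 0}
age_center: 0
dimensions:
  mobility:
    level2: {intercept: -2.9, mobility: 0.040, adl: 0.012, age: 0.010, female: 0.05}
    level3: {intercept: -7.5, mobility: 0.075, adl: 0.020, age: 0.014, female: 0.05}
  self_care:
    level2: {intercept: -3.6, adl: 0.045, mobility: 0.010, age: 0.010, female: 0.02}
    level3: {intercept: -8.0, adl: 0.075, mobility: 0.018, age: 0.013, female: 0.02}
  usual_activities:
    level2: {intercept: -3.0, mobility: 0.022, adl: 0.025, age: 0.009, female: 0.03}
    level3: {intercept: -7.6, mobility: 0.038, adl: 0.042, age: 0.012, female: 0.03}
  pain_discomfort:
    level2: {intercept: -2.6, bodily: 0.038, mobility: 0.012, age: 0.008, female: 0.06}
    level3: {intercept: -7.0, bodily: 0.065, mobility: 0.022, age: 0.011, female: 0.06}
  anxiety_depression:
    level2: {intercept: -2.7, emotional: 0.040, social: 0.010, age: 0.007, female: 0.08}
    level3: {intercept: -7.2, emotional: 0.068, social: 0.018, age: 0.010, female: 0.08}
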