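# EARLYSTIM-like synthetic trial design: two arms (124 stimulation-like,
# 127 medical-therapy-like), visits at baseline/5/12/24 months, mean age
# 52, baseline H&Y capped at 2.5, an 8-point PDQ-39 summary-index
# treatment effect at follow-up, and ~3.6% incomplete cases. Baseline SI
# location/spread and the subscale spread are plausible placeholders (the
# source trial's subscale-level moments are not public).
n_arm_a: 124
n_arm_b: 127
visits: [0, 5, 12, 24]
baseline_si_mean: 32
baseline_si_sd: 12
arm_effect_si: 8
within_subject_corr: 0.6
subscale_spread_sd: 8
age_mean: 52
age_sd: 6
prop_female: 0.40
hy_probs: {"0": 0.02, "1": 0.15, "1.5": 0.18, "2": 0.40, "2.5": 0.25}
hy_si_slope: 6
missing_case_rate: 0.0359
seed: 20260924
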