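# UK EQ-5D-3L time-trade-off value set (the standard MVH/Dolan tariff).
# Additive form: u = 1 - 0.081*[any level > 1] - per-level decrements
# - 0.269*[any level = 3]. Floor (state 33333) = -0.594.
country: UK
label: UK TTO tariff
full_health: 1.0
any_dysfunction: 0.081
extreme: 0.269
decrements:
  mobility: {level2: 0.069, level3: 0.314}
  self_care: {level2: 0.104, level3: 0.214}
  usual_activities: {level2: 0.036, level3: 0.094}
  pain_discomfort: {level2: 0.123, level3: 0.386}
  anxiety_depression: {level2: 0.071, level3: 0.236}
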