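# SYNTHETIC round-number value set for tests and demos; not a published
# national tariff. Floor (state 33333) = 1 - 0.05 - 1.35 - 0.10 = -0.5.
country: TESTLAND
label: synthetic test value set
full_health: 1.0
any_dysfunction: 0.05
extreme: 0.10
decrements:
  mobility: {level2: 0.05, level3: 0.30}
  self_care: {level2: 0.04, level3: 0.25}
  usual_activities: {level2: 0.03, level3: 0.20}
  pain_discomfort: {level2: 0.06, level3: 0.35}
  anxiety_depression: {level2: 0.04, level3: 0.25}
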