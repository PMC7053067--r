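# SYNTHETIC demonstration coefficient set for the ordinal (Cauchit-link)
# mapping family. These are NOT the published Young et al. coefficients
# (which are not reproduced here); they are severity-increasing round
# numbers chosen so that typical PDQ-39 profiles (summary index 20-50)
# span all three response levels. Used by the package's tests and demos.
# To run the published algorithm, transcribe the source coefficients into
# a file of this shape.
family: ordinal
label: synthetic-demo-ordinal
dimensions:
  mobility:
    alpha: [1.4, 3.4]
    beta: {mobility: 0.030, adl: 0.012, bodily: 0.008}
  self_care:
    alpha: [2.2, 4.0]
    beta: {adl: 0.035, mobility: 0.010}
  usual_activities:
    alpha: [1.6, 3.6]
    beta: {mobility: 0.018, adl: 0.020}
  pain_discomfort:
    alpha: [1.2, 3.2]
    beta: {bodily: 0.030, mobility: 0.010}
  anxiety_depression:
    alpha: [1.3, 3.3]
    beta: {emotional: 0.032, social: 0.008}
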