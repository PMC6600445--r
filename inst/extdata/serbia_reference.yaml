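# Reference values for the 11 PTEs studied in Serbian river sediments
# (mg/kg dry weight). `background` is the local background concentration C_n,
# `toxic_response` the dimensionless Hakanson toxic response factor T_r,
# `guideline` the Serbian sediment quality guideline. `min`/`max`/`mean` are
# the study-wide summary statistics of the total (aqua regia) contents.
# Absent values are explicit nulls (~), never zero.
elements:
  Cd: {background: 1.28,  toxic_response: 30, guideline: 3,   min: 1.28,  max: 10.5,  mean: 4.82}
  Co: {background: 8.22,  toxic_response: ~,  guideline: ~,   min: 8.22,  max: 36.2,  mean: 22.0}
  Cr: {background: 62.1,  toxic_response: 2,  guideline: 100, min: 59.8,  max: 230,   mean: 113}
  Cu: {background: 11.5,  toxic_response: 5,  guideline: 100, min: 11.5,  max: 870,   mean: 78.5}
  Fe: {background: 24556, toxic_response: ~,  guideline: ~,   min: 24556, max: 62800, mean: 44177}
  Mn: {background: 648,   toxic_response: ~,  guideline: ~,   min: 648,   max: 3688,  mean: 1399}
  Ni: {background: ~,     toxic_response: 5,  guideline: 50,  min: 33.2,  max: 274,   mean: 77.8}
  Pb: {background: 57.8,  toxic_response: 5,  guideline: 100, min: 57.8,  max: 318,   mean: 132}
  V:  {background: 66.4,  toxic_response: ~,  guideline: ~,   min: 60.4,  max: 149,   mean: 111}
  Zn: {background: 66.6,  toxic_response: 1,  guideline: 300, min: 66.6,  max: 1095,  mean: 353}
  As: {background: ~,     toxic_response: 10, guideline: 25,  min: 3.67,  max: 63.2,  mean: 14.7}
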