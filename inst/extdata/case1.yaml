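# Planning a longitudinal memory study from minimal prior information:
# alternate-forms reliability 0.9, 3-year stability 0.85, T-score scaling.
# Variance components derived from those two coefficients.
design:
  times: [0, 2.5, 5]
params:
  var_i: 90
  var_s: 1.35
  var_e: 10
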