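# Five annual occasions over four years; parameter guesses from a
# literature review.
design:
  times: [0, 1, 2, 3, 4]
  "n": 100
params:
  var_i: 10
  var_s: 1
  var_e: 50
seed: 1
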