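# Published Study A: quarterly measurement for one year, precise instrument.
design:
  times: [0, 0.25, 0.5, 0.75, 1]
  "n": 200
params:
  var_i: 90
  var_s: 3
  var_e: 5.9
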