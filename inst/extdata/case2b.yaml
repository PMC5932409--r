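# Published Study B: same schedule, larger sample, noisier instrument.
design:
  times: [0, 0.25, 0.5, 0.75, 1]
  "n": 300
params:
  var_i: 90
  var_s: 5
  var_e: 10
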