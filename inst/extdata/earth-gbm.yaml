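# Exponential (GBM) growth of the number of living species on Earth:
# 1 form of life 3.5 billion years ago; assumed 5e7 +/- 3e7 species today.
name: earth-gbm
time_unit: yr
boundary:
  ts: -3.5e+09
  Ns: 1
  te: 0
  Ne: 5.0e+07
  dNe: 3.0e+07
family: gbm
grid:
  points: 201
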