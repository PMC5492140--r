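# Phanerozoic genus diversity as a cubic trend: 1 genus 530 Myr ago,
# 4000 +/- 1000 genera today, local maximum 400 Myr ago and local minimum
# 220 Myr ago (Markov-Korotayev-style non-monotonic growth).
name: markov-korotayev-cubic
time_unit: Myr
boundary:
  ts: -530
  Ns: 1
  te: 0
  Ne: 4000
  dNe: 1000
family: cubic
shape:
  tMax: -400
  tmin: -220
grid:
  points: 201
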