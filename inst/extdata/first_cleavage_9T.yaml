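# Example configuration: first-cleavage cell in the 9 T exposure
# condition. Any omitted key keeps its package default.
field:
  B: 9
  direction_angle: 1.5707963267948966
geometry:
  a: 300
  b: 150
spindle:
  center: [60, 30]
  alpha: 0.5
  half_separation: 30
sim:
  t_max: 1500
  n_mt: 50
  seed: 1
  ensemble_n: 20
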