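seed: 42
stages:
  simulate: true
  assemble: true
  damage: true
  contam: true
  classify: true
  tree: true
simulate:
  n_reads: 8000
  mean_fragment_length: 50
  fragment_length_sd: 15
  contamination_fraction: 0.02
  p5_max: 0.35
  p3_max: 0.35
  decay: 0.3
  baseline: 0.001
assemble:
  min_depth: 2
  damage_aware: half
damage:
  window: 25
contam:
  threshold: 0.99
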