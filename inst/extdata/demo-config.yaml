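# demo pipeline configuration: 4 blades x 2 marks (4 KM + 24 KNM pairs)
# plus two held-out query marks, one from blade 1 and one from a new blade
seed: 42
simulation:
  n_blades: 4
  marks_per_blade: 2
  angle_jitter_deg: 3
extraction:
  'n': 5   # quoted: bare n is a YAML 1.1 boolean
  window: 301
  cutoff: 0.06666666666666667
  filter: detrend_lowpass
comparison:
  min_overlap: 0.5
  allow_reverse: true
  cms: true
classification:
  ci_method: t
  conf: 0.95
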