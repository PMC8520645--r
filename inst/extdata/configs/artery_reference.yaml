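# Headline artery scenario: 60 Vp-p / 500 kHz / 60 s, advective lumen blood
# at 0.7 m/s, 0.25 mm voxels.
scenario: artery
grid:
  spacing: 0.00025
  extents: [0.012, 0.014, 0.014]
drive:
  v_pp: 60.0
  frequency: 500000.0
  duration: 60.0
flow:
  velocity: 0.7
  enabled: true
  blood_mode: advective
  direction: 1
solver:
  resolve_dT: 1.0
  resolve_interval: 1.0
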