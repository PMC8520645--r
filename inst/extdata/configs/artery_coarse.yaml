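# Quick-look artery scenario at coarse (0.4 mm) resolution.
scenario: artery
grid:
  spacing: 0.0004
  extents: [0.0104, 0.0104, 0.0104]
drive:
  v_pp: 60.0
  duration: 60.0
flow:
  blood_mode: advective
solver:
  resolve_interval: 2.0
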