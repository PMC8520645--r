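# Sanity scenario: no drive, so the field stays at body temperature and the
# ablation zone is empty.
scenario: artery
grid:
  spacing: 0.0004
  extents: [0.0104, 0.0104, 0.0104]
drive:
  v_pp: 0.0
  duration: 5.0
flow:
  enabled: false
solver:
  resolve_interval: 5.0
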