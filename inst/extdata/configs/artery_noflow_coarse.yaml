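# Coarse artery scenario with static (no-flow) lumen blood; the no-flow
# field is mirror symmetric about the inter-electrode midplane.
scenario: artery
grid:
  spacing: 0.0004
  extents: [0.0104, 0.0104, 0.0104]
drive:
  v_pp: 60.0
  duration: 60.0
flow:
  enabled: false
solver:
  resolve_interval: 2.0
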