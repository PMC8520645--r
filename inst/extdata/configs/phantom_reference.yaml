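# Bench phantom scenario: electrodes resting on a thermochromic gel slab,
# windows facing down, insulated electrical boundary, bench temperature.
scenario: phantom
initial_temperature: 22.0
grid:
  spacing: 0.00025
  extents: [0.009, 0.007, 0.007]
gel_depth: 0.006
drive:
  v_pp: 60.0
  duration: 60.0
flow:
  enabled: false
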