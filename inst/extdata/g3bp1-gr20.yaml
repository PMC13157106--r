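# G3BP1-GR20 constraint preset (global 1-based residue indices over the
# 506-residue complex: G3BP1 = 1-466, GR20 = 467-506).
# Attractive terms promote IDR1-GR20 and IDR1-IDR3 proximity; the
# repulsive term acts within GR20 to prevent peptide self-aggregation.
groups:
  idr1_anchors: [174, 187, 167, 163, 154]
  gr20_anchors: [477, 475, 493, 495, 501]
  idr1_single: [202]
  idr3_single: [452]
  gr20_repl_a: [469, 473, 478, 474]
  gr20_repl_b: [503, 492, 498, 502]
terms:
  - kind: attractive
    group_a: idr1_anchors
    group_b: gr20_anchors
    cutoff: 8.0
    pairing: all_pairs
  - kind: attractive
    group_a: idr1_single
    group_b: idr3_single
    cutoff: 8.0
    pairing: all_pairs
  - kind: repulsive
    group_a: gr20_repl_a
    group_b: gr20_repl_b
    cutoff: 8.0
    pairing: all_pairs
restraint:
  domains: [NTF2L, RRM]
schedule:
  n_steps: 500
  w_c: [1.0, 0.1]
  w_r: [0.0, 1.0]
  interpolation: linear
optimizer:
  step_size: 0.05
  momentum: 0.0
seed: 1
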