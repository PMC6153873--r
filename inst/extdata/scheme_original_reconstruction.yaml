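name: original_reconstruction
steps:
- label: PA
  conditions:
  - ratio: naa_cr
    op: '>'
    cutoff: 4.0
  - ratio: mins_naa
    op: <
    cutoff: 1.35
- label: MB
  conditions:
  - ratio: cr_tcho
    op: <
    cutoff: 0.45
else_label: EP
checks: []
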