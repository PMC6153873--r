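name: updated
steps:
- label: PA
  conditions:
  - ratio: naa_cr
    op: '>'
    cutoff: 2.22
  - ratio: mins_naa
    op: <
    cutoff: 0.65
- label: MB
  conditions:
  - ratio: mins_tcho
    op: <
    cutoff: 0.85
else_label: EP
checks:
- ratio: cr_tcho
  op: <
  cutoff: 0.75
  label: MB
- ratio: naa_tcho
  op: <
  cutoff: 1.0
  label: MB
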