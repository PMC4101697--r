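{
  "name": "DNase-seq secondary",
  "assay_tag": "DNase-seq",
  "steps": [
    {"step": "processed_data", "step_kind": "imported per-sample DHR bed"},
    {"step": "intermediate_step", "step_kind": "merging"},
    {"step": "intermediate_step", "step_kind": "read counting"},
    {"step": "processed_data"}
  ]
}
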