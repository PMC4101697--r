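{
  "name": "DNase-seq primary",
  "assay_tag": "DNase-seq",
  "steps": [
    {"step": "raw_data"},
    {"step": "intermediate_step", "step_kind": "mapping"},
    {"step": "processed_data"}
  ]
}
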