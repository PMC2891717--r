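{
  "n_exposed": 2500,
  "dose_label": "120 ug DDT per vial (nominal LC95)",
  "allele_frequency": 0.28,
  "locus": "Cyp6g1",
  "focal_allele": "BP"
}
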