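{
  "kind": "essential_gene",
  "feature_id": "gene02",
  "residue": 40,
  "to_codon": "TCT",
  "variant": "own_promoter",
  "rbs_boost": false
}
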