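{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "scarless edit specification",
  "type": "object",
  "required": ["kind"],
  "oneOf": [
    {
      "properties": {
        "kind": {"const": "point_mutation"},
        "contig": {"type": "string"},
        "start": {"type": "integer", "minimum": 1},
        "replacement": {"type": "string", "pattern": "^[ACGTacgt]+$"}
      },
      "required": ["kind", "contig", "start", "replacement"]
    },
    {
      "properties": {
        "kind": {"const": "insertion"},
        "contig": {"type": "string"},
        "after": {"type": "integer", "minimum": 1},
        "insert": {"type": "string", "pattern": "^[ACGTacgt]+$"}
      },
      "required": ["kind", "contig", "after", "insert"]
    },
    {
      "properties": {
        "kind": {"const": "deletion"},
        "contig": {"type": "string"},
        "start": {"type": "integer", "minimum": 1},
        "end": {"type": "integer", "minimum": 1}
      },
      "required": ["kind", "contig", "start", "end"]
    },
    {
      "properties": {
        "kind": {"const": "essential_gene"},
        "feature_id": {"type": "string"},
        "residue": {"type": "integer", "minimum": 1},
        "to_codon": {"type": "string", "pattern": "^[ACGTacgt]{3}$"},
        "variant": {"enum": ["own_promoter", "marker_promoter", "wt_restoring"]},
        "rbs_boost": {"type": "boolean"}
      },
      "required": ["kind", "feature_id", "residue", "to_codon", "variant"]
    }
  ]
}
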