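{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "intergen pair run report",
  "type": "object",
  "required": ["pair_id", "parents", "k", "n_candidates", "n_failures",
               "parents_reconstructed", "runtime_s", "config"],
  "properties": {
    "pair_id": {"type": "string"},
    "parents": {"type": "array", "items": {"type": "string"}},
    "k": {"type": "integer"},
    "n_candidates": {"type": "integer"},
    "n_failures": {"type": "integer"},
    "parents_reconstructed": {"type": "boolean"},
    "runtime_s": {"type": "number"},
    "config": {"type": "object"}
  }
}
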