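{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "lavvflow subject report",
  "type": "object",
  "required": ["flow", "provenance"],
  "properties": {
    "flow": {
      "type": "object",
      "required": [
        "forward_volume_ml",
        "total_regurgitant_ml",
        "effective_forward_ml",
        "regurgitant_fraction_pct"
      ],
      "properties": {
        "forward_volume_ml": {"type": "number"},
        "total_regurgitant_ml": {"type": "number"},
        "effective_forward_ml": {"type": "number"},
        "regurgitant_fraction_pct": {"type": "number"},
        "aortic_volume_ml": {"type": "number"},
        "internal_validation_diff_ml": {"type": "number"}
      }
    },
    "jets": {"type": "object"},
    "deltas": {"type": "object"},
    "provenance": {
      "type": "object",
      "required": ["seed", "package_version"],
      "properties": {
        "seed": {"type": "integer"},
        "package_version": {"type": "string"}
      }
    }
  }
}
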