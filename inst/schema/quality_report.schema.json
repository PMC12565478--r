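{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "vctbench quality report",
  "type": "object",
  "required": ["entries", "eval_cs"],
  "properties": {
    "eval_cs": {"type": "string"},
    "masks": {"type": "object"},
    "res_record": {},
    "entries": {
      "type": "array",
      "items": {
        "oneOf": [
          {
            "type": "object",
            "required": ["metric", "class", "value", "mask_id",
                         "normalization", "hyperparameters", "eval_cs"],
            "properties": {
              "metric": {"type": "string"},
              "class": {"enum": ["QFR", "QTF", "QTM"]},
              "value": {"type": ["number", "string", "null"]},
              "uncertainty": {},
              "detail": {},
              "mask_id": {"type": "string"},
              "normalization": {"type": "object"},
              "hyperparameters": {"type": "object"},
              "eval_cs": {"type": "string"}
            }
          },
          {
            "type": "object",
            "required": ["metric", "failed", "reason"],
            "properties": {
              "metric": {"type": "string"},
              "failed": {"const": true},
              "reason": {"type": "string"}
            }
          }
        ]
      }
    }
  }
}
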