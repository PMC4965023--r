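{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "spinemorph contour file",
  "description": "Per-subject endplate boundary contours in a right-handed RAS frame (+x patient right, +y anterior, +z cranial), millimetres. S1 contributes only its superior endplate (the sacral plate).",
  "type": "object",
  "required": ["subject_id", "frame", "levels"],
  "properties": {
    "subject_id": {"type": "string"},
    "frame": {"const": "RAS-mm"},
    "levels": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["level", "side", "points", "canal_centroid"],
        "properties": {
          "level": {"enum": ["T1","T2","T3","T4","T5","T6","T7","T8","T9","T10","T11","T12","L1","L2","L3","L4","L5","S1"]},
          "side": {"enum": ["superior", "inferior"]},
          "points": {
            "type": "array", "minItems": 12,
            "items": {"type": "array", "minItems": 3, "maxItems": 3,
                      "items": {"type": "number"}}
          },
          "canal_centroid": {"type": "array", "minItems": 3, "maxItems": 3,
                             "items": {"type": "number"}}
        }
      }
    }
  }
}
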