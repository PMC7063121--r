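{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "orthomon session sidecar",
  "type": "object",
  "required": ["participant", "maneuver", "rep_idx", "pre_aligned",
               "channels"],
  "properties": {
    "participant": {"type": ["integer", "string"]},
    "maneuver": {"type": "string"},
    "rep_idx": {"type": "integer", "minimum": 1},
    "pre_aligned": {"type": "boolean"},
    "channels": {
      "type": "object",
      "required": ["device", "channel", "fs", "t0", "units", "file"],
      "properties": {
        "device": {"type": "array", "items": {"type": "string"}},
        "channel": {"type": "array", "items": {"type": "string"}},
        "fs": {"type": "array", "items": {"type": "number",
                                          "exclusiveMinimum": 0}},
        "t0": {"type": "array", "items": {"type": "number"}},
        "units": {"type": "array", "items": {"type": "string"}},
        "file": {"type": "array", "items": {"type": "string"}}
      }
    }
  }
}
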