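{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Pointing-session JSON dialect, format_version 1",
  "description": "One participant-day of egocentric pointing trials. Readers must be forward-tolerant of unknown keys. Pointing vectors are unit 3-vectors in East/North/Up world coordinates.",
  "type": "object",
  "required": ["format_version", "participant", "day", "layout", "roster", "trials"],
  "properties": {
    "format_version": { "const": 1 },
    "participant": {
      "type": "object",
      "required": ["id", "handedness", "pointing_hand", "rotation_side"],
      "properties": {
        "id": { "type": "string" },
        "sex": { "type": ["string", "null"] },
        "birthdate": { "type": ["string", "null"] },
        "handedness": { "enum": ["left", "right"] },
        "pointing_hand": { "enum": ["left", "right"] },
        "rotation_side": { "enum": ["left", "right"] }
      }
    },
    "day": { "enum": [1, 2] },
    "layout": {
      "type": "object",
      "required": ["width_m", "depth_m", "height_m", "observer_xy", "eye_height_m", "facing_heading_deg"],
      "properties": {
        "width_m": { "type": "number", "exclusiveMinimum": 0 },
        "depth_m": { "type": "number", "exclusiveMinimum": 0 },
        "height_m": { "type": "number", "exclusiveMinimum": 0 },
        "observer_xy": { "type": "array", "items": { "type": "number" }, "minItems": 2, "maxItems": 2 },
        "eye_height_m": { "type": "number", "exclusiveMinimum": 0 },
        "facing_heading_deg": { "type": "number" }
      }
    },
    "roster": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["name", "azimuth_deg", "elevation_deg", "side"],
        "properties": {
          "name": { "type": "string" },
          "position_xyz_m": { "type": "array", "items": { "type": "number" }, "minItems": 3, "maxItems": 3 },
          "azimuth_deg": { "type": "number", "exclusiveMinimum": -180, "maximum": 180 },
          "elevation_deg": { "type": "number", "minimum": -90, "maximum": 90 },
          "side": { "enum": ["left", "right", "center"] },
          "analyse_azimuth": { "type": "boolean" }
        }
      }
    },
    "trials": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["index", "day", "condition", "target", "repetition", "vector"],
        "properties": {
          "index": { "type": "integer", "minimum": 0 },
          "day": { "enum": [1, 2] },
          "condition": { "enum": ["EO", "EC", "RR", "MR"] },
          "target": { "type": "string" },
          "repetition": { "type": "integer", "minimum": 1 },
          "vector": {
            "type": "array",
            "items": { "type": "number", "minimum": -1, "maximum": 1 },
            "minItems": 3,
            "maxItems": 3
          },
          "flags": { "type": "string" },
          "timestamp": { "type": ["string", "null"] },
          "gps": {}
        }
      }
    }
  }
}
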