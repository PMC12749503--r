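{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "Pose keypoint timeline",
  "description": "Per-frame normalized 33-landmark pose coordinates with video metadata. x/y are fractions of frame width/height (image convention, y increases downward); z is a relative depth and is optional; visibility is a detection confidence in [0,1].",
  "type": "object",
  "required": ["Timeline", "TotalNumberOfFrames", "Width", "Height", "AverageFPS"],
  "properties": {
    "Timeline": {
      "type": "object",
      "required": ["Items"],
      "properties": {
        "Items": {
          "type": "array",
          "items": {
            "type": "object",
            "required": ["Index", "Landmarks"],
            "properties": {
              "Index": {"type": "integer", "minimum": 0},
              "Landmarks": {
                "type": "array",
                "minItems": 33,
                "maxItems": 33,
                "items": {
                  "type": "object",
                  "required": ["x", "y", "visibility"],
                  "properties": {
                    "x": {"type": "number"},
                    "y": {"type": "number"},
                    "z": {"type": "number"},
                    "visibility": {"type": "number", "minimum": 0, "maximum": 1}
                  }
                }
              }
            }
          }
        }
      }
    },
    "TotalNumberOfFrames": {"type": "integer", "minimum": 0},
    "Width": {"type": "number", "exclusiveMinimum": 0},
    "Height": {"type": "number", "exclusiveMinimum": 0},
    "AverageFPS": {"type": "number", "exclusiveMinimum": 0}
  }
}
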