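{
  "$schema": "https://json-schema.org/draft/2020-12/schema",
  "title": "equitag facility scenario configuration",
  "type": "object",
  "required": ["horses"],
  "properties": {
    "horses": {
      "type": "array",
      "minItems": 1,
      "items": {
        "type": "object",
        "required": ["id", "stall", "aisle", "weekday_pasture"],
        "properties": {
          "id": {"type": "string"},
          "stall": {"type": "integer"},
          "aisle": {"type": "string"},
          "weekday_pasture": {"type": "string"},
          "weekend_pasture": {"type": "string"},
          "use": {"type": "string"}
        }
      }
    },
    "people": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": {"type": "string"},
          "shift_start_s": {"type": "integer", "minimum": 0, "maximum": 86400},
          "shift_end_s": {"type": "integer", "minimum": 0, "maximum": 86400},
          "days": {"type": "array", "items": {"type": "integer", "minimum": 1}}
        }
      }
    },
    "static_tags": {
      "type": "array",
      "items": {
        "type": "object",
        "required": ["id"],
        "properties": {
          "id": {"type": "string"},
          "kind": {
            "type": "string",
            "enum": ["pasture", "barn_door", "aisle", "arena", "wash_stall",
                     "grooming_stall", "cross_tie", "tack_room", "feed_room",
                     "other"]
          },
          "link": {"type": "string",
                   "description": "pasture id or aisle label the tag belongs to"}
        }
      }
    },
    "bookkeeping_tag_id": {"type": "string", "default": "bookkeeping"},
    "n_days": {"type": "integer", "minimum": 1, "default": 7},
    "day0_weekday": {
      "type": "string", "default": "Tuesday",
      "enum": ["Monday", "Tuesday", "Wednesday", "Thursday", "Friday",
               "Saturday", "Sunday"]
    },
    "turnout_start_s": {"type": "integer", "default": 30600},
    "turnout_end_s": {"type": "integer", "default": 59400},
    "weekend_days": {"type": "array", "items": {"type": "integer"},
                     "default": [4, 5]},
    "params": {
      "type": "object",
      "properties": {
        "stall_bout_on_s": {"type": "number", "default": 1800},
        "stall_bout_off_s": {"type": "number", "default": 7200},
        "transit_s": {"type": "integer", "default": 60},
        "p_train": {"type": "number", "minimum": 0, "maximum": 1, "default": 0.8},
        "train_mean_s": {"type": "number", "default": 2400},
        "train_window_s": {"type": "array", "items": {"type": "integer"},
                           "default": [61200, 72000]},
        "person_transits_per_day": {"type": "integer", "default": 4}
      }
    }
  }
}
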