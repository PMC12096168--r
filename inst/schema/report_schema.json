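{
  "title": "healthequity pipeline report",
  "type": "object",
  "required": [
    "n",
    "outcome_rate",
    "cleaning_report",
    "screen",
    "importance",
    "selected_factors",
    "coefficients",
    "odds_ratios",
    "equity",
    "decomposition",
    "seed"
  ],
  "properties": {
    "n": { "type": "integer", "minimum": 1 },
    "outcome_rate": { "type": "number", "minimum": 0, "maximum": 1 },
    "cleaning_report": { "type": "object" },
    "screen": { "type": "array" },
    "importance": { "type": "array" },
    "lambda": { "type": "number" },
    "selected_factors": { "type": "array", "items": { "type": "string" } },
    "coefficients": { "type": "object" },
    "odds_ratios": { "type": "array" },
    "equity": {
      "type": "object",
      "required": ["ci", "mu", "residual_term"],
      "properties": {
        "ci": { "type": "number" },
        "mu": { "type": "number" },
        "residual_term": { "type": "number" }
      }
    },
    "decomposition": { "type": "array" },
    "seed": { "type": "integer" }
  }
}
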