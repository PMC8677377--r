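{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "movewarp comparison report",
  "description": "Result of comparing a learner's periodic movement recording against an expert's. Sample indices are 1-based.",
  "type": "object",
  "required": ["period_expert", "period_learner", "periods_equal", "m", "b",
               "r_squared", "mean_line_diff", "verdict", "reasons",
               "thresholds", "path_method"],
  "properties": {
    "period_expert":   {"type": "integer", "description": "expert cycle length, samples (spacing - 1 convention)"},
    "period_learner":  {"type": "integer"},
    "spacing_expert":  {"type": "integer", "description": "raw median maxima spacing of the expert's Pearson profile"},
    "spacing_learner": {"type": "integer"},
    "periods_equal":   {"type": "boolean"},
    "m":               {"type": "number", "nullable": true, "description": "slope of the warping-path regression"},
    "b":               {"type": "number", "nullable": true, "description": "intercept"},
    "r_squared":       {"type": "number", "nullable": true},
    "mean_line_diff":  {"type": "number", "nullable": true, "description": "mean |fitted line - ideal line y=x| over the window"},
    "shift_applied":   {"type": "integer", "nullable": true, "description": "learner head-drop from phase synchronization"},
    "common_length":   {"type": "integer", "nullable": true},
    "low_confidence":  {"type": "boolean", "nullable": true, "description": "sync correlation below 0.2"},
    "verdict":         {"type": "string", "enum": ["similar", "different"]},
    "reasons":         {"type": "array", "description": "failed criteria: period, r_squared, line_difference"},
    "window":          {"type": "object", "nullable": true, "description": "initial_sample, final_sample, k, sample_limit, seed"},
    "discrepant_segments": {"type": "array", "description": "objects {start, end}: sample ranges exceeding the cost band"},
    "thresholds":      {"type": "object", "description": "diff_max, r2_min"},
    "path_method":     {"type": "string", "enum": ["greedy", "dp"]}
  }
}
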