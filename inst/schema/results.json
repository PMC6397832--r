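{
  "$schema": "http://json-schema.org/draft-07/schema#",
  "title": "idasense analysis results",
  "type": "object",
  "required": ["seed"],
  "properties": {
    "seed": {"type": "integer"},
    "classification_rate": {"type": "number"},
    "trend_spearman": {"type": "number"},
    "n_observations": {"type": "integer"},
    "n_classes": {"type": "integer"},
    "confusion": {"type": "array"},
    "anova_ranking": {"type": "array"},
    "rmse": {"type": "object"},
    "binding_constants": {"type": "array"},
    "config_hash": {"type": "string"}
  }
}
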