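{
  "required_columns": {
    "arm": "string",
    "rb_ratio": "number",
    "total_intensity": "number",
    "norm_amplitude_mean": "number",
    "norm_amplitude_sd": "number",
    "period_mean": "number",
    "period_sd": "number",
    "n": "integer"
  }
}
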