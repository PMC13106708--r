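{
  "required_columns": {
    "wavelength": "number",
    "genotype": "string",
    "amplitude_mean": "number",
    "amplitude_sd": "number",
    "period_mean": "number",
    "period_sd": "number",
    "fit_mode": "string",
    "n": "integer"
  }
}
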