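{
  "required_columns": {
    "genotype": "string",
    "seed": "integer",
    "f0_R": "number",
    "f0_FR": "number",
    "pk_R": "number",
    "pk_FR": "number",
    "band_correlation": "number"
  }
}
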