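{
  "required_columns": {
    "wavelength": "number",
    "genotype": "string",
    "pulsed_pk_mean": "number",
    "pulsed_pk_sd": "number",
    "constant_pk_mean": "number",
    "constant_pk_sd": "number",
    "entrainment_index_mean": "number",
    "pulsed_f0_mean": "number",
    "n": "integer"
  }
}
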