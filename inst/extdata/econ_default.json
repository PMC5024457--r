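{
  "biopsy_histology_cost": 86,
  "kit_cost": 20,
  "tariff_delta": 38,
  "currency_label": "£"
}
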