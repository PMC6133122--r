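{
  "version": "1.0",
  "description": "Published four-metabolite urine rejection-score model. Coefficients apply to creatinine-normalized, log-transformed, centered and scaled signal intensities (I_x). Standardization constants are those of whatever training run produced the features; the published training constants were never released, so none are shipped.",
  "intercept": -3.0048615,
  "coefficients": {
    "Alanine": -0.2527461,
    "Citrate": -0.8224731,
    "Lactate": 0.9502339,
    "Urea": 0.2529190
  },
  "feature_order": ["Alanine", "Citrate", "Lactate", "Urea"],
  "standardization": null
}
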