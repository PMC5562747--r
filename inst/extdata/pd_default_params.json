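{
  "description": "Packaged default pharmacodynamic parameters for the competitive-antagonism beat-rate model, calibrated by weighted least squares against the anchor percent-changes listed under anchors. Calibrated values, not measurements.",
  "parameters": {
    "B0_bpm": 54,
    "Rmax": 0.55585325336882,
    "EC50_uM": 0.150510441595845,
    "Ki_uM": 0.026405717912196,
    "hill_n": 5.44958447648773,
    "E_basal_uM": 0.116697711779262
  },
  "anchors": [
    {
      "condition": "epinephrine_alone",
      "E_uM": 0.5,
      "P_uM": 0,
      "target_pct": 40,
      "weight": 1,
      "fitted_pct": 39.999999702529,
      "residual_pct": -2.97470982957293e-07
    },
    {
      "condition": "propranolol_alone",
      "E_uM": 0,
      "P_uM": 0.1,
      "target_pct": -10,
      "weight": 1,
      "fitted_pct": -9.99999999913146,
      "residual_pct": 8.68535465770037e-10
    },
    {
      "condition": "liver_cleared_block",
      "E_uM": 0.5,
      "P_uM": 0.0662337782140526,
      "target_pct": 25,
      "weight": 1,
      "fitted_pct": 24.9999999236534,
      "residual_pct": -7.63466054820583e-08
    },
    {
      "condition": "full_block",
      "E_uM": 0.5,
      "P_uM": 0.1,
      "target_pct": 5,
      "weight": 0.5,
      "fitted_pct": 4.99999995732695,
      "residual_pct": -4.26730499825112e-08
    }
  ],
  "rss": 9.52290388214714e-14
}
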