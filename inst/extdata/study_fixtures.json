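{
  "fixture_version": "1.0.0",
  "compounds": {
    "oxycodone": {
      "name": "oxycodone",
      "logP": 0.255,
      "mw": 315.36,
      "pka_acid": 13.56,
      "pka_base": 8.21,
      "fu_plasma": 0.55,
      "bp_ratio": 1.0465,
      "clearance": 28.3,
      "kp_tissue": 5.29,
      "f_oral": 0.735,
      "f_derm": 0.3312,
      "ka_oral": 0.8281,
      "k_perm_total": 1.0e-4
    },
    "buprenorphine": {
      "name": "buprenorphine",
      "logP": 4.98,
      "mw": 467.64,
      "pka_acid": 7.5,
      "pka_base": 12.54,
      "fu_plasma": 0.04,
      "bp_ratio": 0.55,
      "clearance": 85.5,
      "kp_tissue": 13.3464,
      "f_oral": null,
      "f_derm": 0.15,
      "ka_oral": null,
      "k_perm_total": 5.93e-4
    }
  },
  "regimens": {
    "oxycodone_iv": {
      "route": "IV",
      "dose_mg": 6.75,
      "sim_duration_h": 24
    },
    "oxycodone_oral": {
      "route": "ORAL",
      "dose_mg": 15,
      "sim_duration_h": 24
    },
    "oxycodone_td": {
      "route": "TD",
      "dose_mg": 70.2,
      "surface_area_cm2": 120,
      "wear_duration_h": 72,
      "sim_duration_h": 96
    },
    "buprenorphine_iv": {
      "route": "IV",
      "dose_mg": 1.2,
      "sim_duration_h": 24
    },
    "buprenorphine_td": {
      "route": "TD",
      "dose_mg": 1.68,
      "surface_area_cm2": 12.5,
      "wear_duration_h": 168,
      "sim_duration_h": 192
    }
  },
  "skin_params": {
    "oxycodone": {
      "k_sc_water": 3.73,
      "k_de_water": 10.29,
      "raw_resistance": { "sc": 9952.99, "ve": 1.21, "de": 45.49 }
    },
    "buprenorphine": {
      "k_sc_water": 5.29,
      "k_de_water": 57.29,
      "raw_resistance": { "sc": 641.39, "ve": 26.98, "de": 1011.71 }
    }
  },
  "fold_error_cells": [
    {"compound": "buprenorphine", "route": "IV", "metric": "auc_0t", "calculated": 17.45, "predicted": 14.83, "aafe_printed": 1.18, "afe_printed": 1.18, "rounding_limited": false},
    {"compound": "buprenorphine", "route": "IV", "metric": "cmax", "calculated": 38.16, "predicted": 36.76, "aafe_printed": 1.04, "afe_printed": 1.04, "rounding_limited": false},
    {"compound": "buprenorphine", "route": "IV", "metric": "tmax", "calculated": 0.04, "predicted": 0.04, "aafe_printed": 1.00, "afe_printed": 1.00, "rounding_limited": false},
    {"compound": "buprenorphine", "route": "TD", "metric": "auc_0t", "calculated": 25.99, "predicted": 26.27, "aafe_printed": 1.01, "afe_printed": 0.99, "rounding_limited": false},
    {"compound": "buprenorphine", "route": "TD", "metric": "cmax", "calculated": 0.20, "predicted": 0.20, "aafe_printed": 1.03, "afe_printed": 1.03, "rounding_limited": true},
    {"compound": "buprenorphine", "route": "TD", "metric": "tmax", "calculated": 48.02, "predicted": 37.99, "aafe_printed": 1.26, "afe_printed": 1.26, "rounding_limited": false},
    {"compound": "oxycodone", "route": "IV", "metric": "auc_0t", "calculated": 153.10, "predicted": 161.28, "aafe_printed": 1.05, "afe_printed": 0.95, "rounding_limited": false},
    {"compound": "oxycodone", "route": "IV", "metric": "cmax", "calculated": 30.73, "predicted": 38.41, "aafe_printed": 1.25, "afe_printed": 0.80, "rounding_limited": false},
    {"compound": "oxycodone", "route": "IV", "metric": "tmax", "calculated": 0.43, "predicted": 0.43, "aafe_printed": 1.00, "afe_printed": 1.00, "rounding_limited": false},
    {"compound": "oxycodone", "route": "ORAL", "metric": "auc_0t", "calculated": 180.29, "predicted": 208.86, "aafe_printed": 1.16, "afe_printed": 0.86, "rounding_limited": false},
    {"compound": "oxycodone", "route": "ORAL", "metric": "cmax", "calculated": 33.26, "predicted": 29.95, "aafe_printed": 1.11, "afe_printed": 1.11, "rounding_limited": false},
    {"compound": "oxycodone", "route": "ORAL", "metric": "tmax", "calculated": 1.19, "predicted": 0.86, "aafe_printed": 1.39, "afe_printed": 1.39, "rounding_limited": true},
    {"compound": "oxycodone", "route": "TD", "metric": "auc_0t", "calculated": 214.01, "predicted": 220.04, "aafe_printed": 1.03, "afe_printed": 0.97, "rounding_limited": false},
    {"compound": "oxycodone", "route": "TD", "metric": "cmax", "calculated": 3.20, "predicted": 3.26, "aafe_printed": 1.02, "afe_printed": 0.98, "rounding_limited": false},
    {"compound": "oxycodone", "route": "TD", "metric": "tmax", "calculated": 47.99, "predicted": 27.25, "aafe_printed": 1.76, "afe_printed": 1.76, "rounding_limited": false}
  ],
  "fold_error_columns": [
    {"compound": "buprenorphine", "route": "IV", "gmfe_printed": 1.07, "p_value_printed": 0.4474, "rounding_limited": false},
    {"compound": "buprenorphine", "route": "TD", "gmfe_printed": 1.10, "p_value_printed": 0.0112, "rounding_limited": true},
    {"compound": "oxycodone", "route": "IV", "gmfe_printed": 1.10, "p_value_printed": 0.7468, "rounding_limited": false},
    {"compound": "oxycodone", "route": "ORAL", "gmfe_printed": 1.21, "p_value_printed": 0.1666, "rounding_limited": false},
    {"compound": "oxycodone", "route": "TD", "gmfe_printed": 1.23, "p_value_printed": 0.8696, "rounding_limited": false}
  ]
}
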