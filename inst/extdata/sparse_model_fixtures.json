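{
  "neutropenia": {
    "phenotype": "288.11",
    "auc": 0.76,
    "weights": {
      "Number of QRS Complexes": 0.55,
      "QRS Duration in aVF": -0.36,
      "P + P' Duration in aVF": -0.24,
      "Q Amplitude in aVF": 0.17
    },
    "intercept": -4.88
  },
  "respiratory_failure": {
    "phenotype": "509",
    "auc": 0.75,
    "weights": {
      "Number of QRS Complexes": 0.53,
      "QTc dispersion": 0.25,
      "T Amplitude in aVR": 0.24,
      "QRS total peak to peak amplitude in aVR": -0.21,
      "P + P' Duration in V4": -0.20
    },
    "intercept": -3.52
  },
  "lung_transplant": {
    "phenotype": "519",
    "auc": 0.77,
    "weights": {
      "Mean QTc": -0.63,
      "PR interval in aVR": -0.51,
      "PR segment in V2": -0.38,
      "S Amplitude in aVL": -0.27,
      "P Amplitude in II": 0.26,
      "Number of QRS Complexes": 0.05
    },
    "intercept": -6.30
  },
  "menstrual_disorders": {
    "phenotype": "626",
    "auc": 0.78,
    "weights": {
      "QRS total peak to peak amplitude in V4": -0.72,
      "PR interval in aVR": -0.40,
      "T Amplitude in I": 0.39,
      "Mean QRS duration": -0.23,
      "R Amplitude in II": 0.20,
      "P + P' Duration in V6": -0.20,
      "S Amplitude in V1": -0.15
    },
    "intercept": -6.75
  },
  "ascites": {
    "phenotype": "577.2",
    "auc": 0.75,
    "weights": {
      "QRS total peak to peak amplitude in V5": -0.64,
      "Number of QRS Complexes": 0.40
    },
    "intercept": -5.61
  }
}
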