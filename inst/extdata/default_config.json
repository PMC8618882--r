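{
  "n_subjects": 205,
  "rho_latent": 0.43,
  "include_zero_sample": true,
  "seed": 1,
  "missing": {
    "astringency": [1, 2, 3, 4, 5, 6, 7, 8],
    "pungency": [1, 2, 3, 4, 5, 6],
    "cooling": [1, 2, 3, 4, 5, 7, 9],
    "taste": [1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12, 13, 14, 15, 16]
  },
  "chem_profiles": {
    "astringency": [
      {
        "modality": "astringency",
        "cluster": 1,
        "size": 91,
        "means": [1.05, 1.08, 1.78, 4.03, 6.21],
        "sds": [1.02, 1.11, 1.41, 1.72, 1.81]
      },
      {
        "modality": "astringency",
        "cluster": 2,
        "size": 62,
        "means": [0.86, 1.18, 4.47, 7, 8.63],
        "sds": [0.95, 1.11, 1.33, 1.55, 1.1]
      },
      {
        "modality": "astringency",
        "cluster": 3,
        "size": 44,
        "means": [3.58, 4.71, 4.83, 7.19, 8.18],
        "sds": [2.25, 2.15, 2.57, 1.55, 1.4]
      }
    ],
    "pungency": [
      {
        "modality": "pungency",
        "cluster": 1,
        "size": 56,
        "means": [1.04, 1.21, 2.01, 2.97, 5.18],
        "sds": [1.05, 1.08, 1.51, 1.61, 1.57]
      },
      {
        "modality": "pungency",
        "cluster": 2,
        "size": 59,
        "means": [0.84, 1.03, 1.97, 4.98, 8.15],
        "sds": [0.76, 1.01, 1.28, 1.71, 0.82]
      },
      {
        "modality": "pungency",
        "cluster": 3,
        "size": 84,
        "means": [2.5, 3.46, 5.06, 7.09, 8.75],
        "sds": [1.94, 1.86, 1.7, 1.72, 1.1]
      }
    ],
    "cooling": [
      {
        "modality": "cooling",
        "cluster": 1,
        "size": 81,
        "means": [0.67, 1.47, 1.75, 2.59, 3.99],
        "sds": [0.97, 1.12, 1.13, 1.59, 1.66]
      },
      {
        "modality": "cooling",
        "cluster": 2,
        "size": 96,
        "means": [1.96, 3.01, 3.92, 5.06, 6.32],
        "sds": [1.38, 1.73, 1.54, 1.44, 1.47]
      },
      {
        "modality": "cooling",
        "cluster": 3,
        "size": 21,
        "means": [3.76, 4.7, 6.54, 8.06, 8.78],
        "sds": [1.51, 1.94, 1.61, 1.69, 0.97]
      }
    ]
  },
  "taste_profiles": {
    "sour": [
      {
        "modality": "sour",
        "cluster": 1,
        "size": 57,
        "means": [0.9, 1.4, 2.2, 3.5, 5],
        "sds": [1.5, 1.5, 1.5, 1.5, 1.5]
      },
      {
        "modality": "sour",
        "cluster": 2,
        "size": 95,
        "means": [1.5, 2.5, 4, 5.8, 7.5],
        "sds": [1.5, 1.5, 1.5, 1.5, 1.5]
      },
      {
        "modality": "sour",
        "cluster": 3,
        "size": 37,
        "means": [3, 4.5, 6, 7.6, 8.8],
        "sds": [1.5, 1.5, 1.5, 1.5, 1.5]
      }
    ],
    "sweet": [
      {
        "modality": "sweet",
        "cluster": 1,
        "size": 52,
        "means": [0.9, 1.4, 2.2, 3.5, 5],
        "sds": [1.5, 1.5, 1.5, 1.5, 1.5]
      },
      {
        "modality": "sweet",
        "cluster": 2,
        "size": 88,
        "means": [1.5, 2.5, 4, 5.8, 7.5],
        "sds": [1.5, 1.5, 1.5, 1.5, 1.5]
      },
      {
        "modality": "sweet",
        "cluster": 3,
        "size": 49,
        "means": [3, 4.5, 6, 7.6, 8.8],
        "sds": [1.5, 1.5, 1.5, 1.5, 1.5]
      }
    ],
    "umami": [
      {
        "modality": "umami",
        "cluster": 1,
        "size": 70,
        "means": [0.9, 1.4, 2.2, 3.5, 5],
        "sds": [1.5, 1.5, 1.5, 1.5, 1.5]
      },
      {
        "modality": "umami",
        "cluster": 2,
        "size": 83,
        "means": [1.5, 2.5, 4, 5.8, 7.5],
        "sds": [1.5, 1.5, 1.5, 1.5, 1.5]
      },
      {
        "modality": "umami",
        "cluster": 3,
        "size": 36,
        "means": [3, 4.5, 6, 7.6, 8.8],
        "sds": [1.5, 1.5, 1.5, 1.5, 1.5]
      }
    ],
    "bitter": [
      {
        "modality": "bitter",
        "cluster": 1,
        "size": 60,
        "means": [0.9, 1.4, 2.2, 3.5, 5],
        "sds": [1.5, 1.5, 1.5, 1.5, 1.5]
      },
      {
        "modality": "bitter",
        "cluster": 2,
        "size": 90,
        "means": [1.5, 2.5, 4, 5.8, 7.5],
        "sds": [1.5, 1.5, 1.5, 1.5, 1.5]
      },
      {
        "modality": "bitter",
        "cluster": 3,
        "size": 39,
        "means": [3, 4.5, 6, 7.6, 8.8],
        "sds": [1.5, 1.5, 1.5, 1.5, 1.5]
      }
    ],
    "salty": [
      {
        "modality": "salty",
        "cluster": 1,
        "size": 55,
        "means": [0.9, 1.4, 2.2, 3.5, 5],
        "sds": [1.5, 1.5, 1.5, 1.5, 1.5]
      },
      {
        "modality": "salty",
        "cluster": 2,
        "size": 92,
        "means": [1.5, 2.5, 4, 5.8, 7.5],
        "sds": [1.5, 1.5, 1.5, 1.5, 1.5]
      },
      {
        "modality": "salty",
        "cluster": 3,
        "size": 42,
        "means": [3, 4.5, 6, 7.6, 8.8],
        "sds": [1.5, 1.5, 1.5, 1.5, 1.5]
      }
    ]
  }
}
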