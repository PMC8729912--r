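{
  "comment": "Lupas-style heptad propensity table, prgscan version 1. Columns are heptad positions a-g. Hydrophobic residues favour the core positions a/d, charged and polar residues the outer positions; proline and glycine are penalized everywhere. The Gaussian window-score parameters are calibrated to this table for the default window of 21.",
  "window": 21,
  "gauss_cc": [1.85, 0.18],
  "gauss_glob": [0.90, 0.22],
  "p_cutoff": 0.5,
  "min_run": 14,
  "propensities": {
    "A": [1.60, 1.00, 1.00, 1.30, 1.00, 0.95, 1.00],
    "R": [0.45, 1.35, 1.30, 0.50, 1.40, 1.30, 1.40],
    "N": [0.45, 1.15, 1.15, 0.50, 1.20, 1.15, 1.10],
    "D": [0.25, 1.20, 1.25, 0.30, 1.25, 1.20, 1.15],
    "C": [0.90, 0.70, 0.70, 0.85, 0.70, 0.70, 0.70],
    "Q": [0.40, 1.45, 1.40, 0.45, 1.50, 1.40, 1.45],
    "E": [0.30, 1.60, 1.55, 0.35, 1.65, 1.50, 1.55],
    "G": [0.40, 0.60, 0.60, 0.40, 0.60, 0.60, 0.60],
    "H": [0.60, 0.95, 0.95, 0.65, 1.00, 0.95, 0.95],
    "I": [2.60, 0.40, 0.40, 2.20, 0.50, 0.40, 0.45],
    "L": [3.17, 0.40, 0.45, 3.90, 0.55, 0.45, 0.50],
    "K": [0.35, 1.50, 1.45, 0.40, 1.55, 1.45, 1.60],
    "M": [2.20, 0.60, 0.60, 1.90, 0.65, 0.60, 0.60],
    "F": [1.60, 0.45, 0.50, 1.30, 0.55, 0.50, 0.50],
    "P": [0.08, 0.12, 0.12, 0.08, 0.12, 0.12, 0.12],
    "S": [0.55, 1.05, 1.05, 0.60, 1.05, 1.05, 1.00],
    "T": [0.60, 1.00, 1.00, 0.65, 1.00, 1.00, 0.95],
    "W": [0.80, 0.55, 0.55, 0.70, 0.60, 0.55, 0.55],
    "Y": [0.90, 0.80, 0.80, 0.85, 0.85, 0.80, 0.80],
    "V": [1.80, 0.45, 0.45, 1.40, 0.50, 0.45, 0.50]
  }
}
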