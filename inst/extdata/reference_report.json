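{
  "package_version": "0.1.0",
  "seed": 42,
  "config_hash": "fe85218a",
  "counts": {
    "cells": 60,
    "frames_per_cell": 150,
    "corrected_frames": 117,
    "dip_cells": 11,
    "stable_rmsd_cells": 49,
    "periodic_cells": 0
  },
  "qc": {
    "correction_rate": 0.013,
    "reference_error_rate": 0.0142857142857143
  },
  "fractions": {
    "label": ["stable", "dip", "shallow_dip", "shift"],
    "n": [40, 11, 6, 3],
    "fraction": [0.666666666666667, 0.183333333333333, 0.1, 0.05]
  },
  "population": {
    "quantity": ["ratio", "atp"],
    "n": [60, 60],
    "mean": [0.977840504341408, 3.91136201736563],
    "sd": [0.0795685389766737, 0.318274155906695],
    "cv": [0.0813716946919319, 0.0813716946919319]
  },
  "rmsd": {
    "n_dip": 11,
    "n_stable": 49,
    "mean_max_fold": 4.74952188742659,
    "median_max_fold": 4.94699228451792,
    "frac_fold_gt3": 0.818181818181818,
    "mean_stable_rmsd": 24.6415793375107
  },
  "periods": {
    "n_significant": 0,
    "median_period_min": null
  }
}
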