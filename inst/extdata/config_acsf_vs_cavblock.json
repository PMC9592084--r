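{
  "seed": 1,
  "tcspc": {
    "laser_period_ns": 12.5,
    "n_bins": 256,
    "irf": {"center_ns": 1.5, "sigma_ns": 0.2, "mode": "fixed"},
    "fit": {"components": 2, "window_ns": 8, "objective": "poisson"}
  },
  "unmixing": {"ratio": 0.053},
  "thresholds": {"min_delta_rcamp": 0.2, "max_half_decay": 35, "baseline_window": 60},
  "calibration": {"kd": 26, "na_rest": 13, "quench_amplitude_a": 0.74},
  "pumps": {"alpha1beta1": {"k_half": 13, "hill_n": 3}},
  "synthexp": {"preset": "acsf_vs_cavblock", "n_cells": 13, "t_end": 420, "render_photons": false}
}
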