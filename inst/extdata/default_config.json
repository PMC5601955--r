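{
  "protocol": {
    "sampling_rate": 2000,
    "n_channels": 16,
    "bit_depth": 16,
    "n_repetitions": 3,
    "contraction_s": 4,
    "rest_s": 4,
    "gain": 200
  },
  "activation": {
    "overlap": 0,
    "baseline_noise_rms": 5e-06,
    "mvc_fraction": 0.7,
    "ramp_fraction": 0.15,
    "mvc_rms": 0.002
  },
  "frontend": {
    "hp_order": 1,
    "hp_cutoff_hz": 1,
    "lp_order": 3,
    "lp_cutoff_hz": 750,
    "gain": 200,
    "bits": 16,
    "fullscale_v": 2.5
  },
  "segmentation": {
    "trim_fraction": 0.15,
    "window_ms": 200,
    "increment_ms": 50,
    "convention": "drop_ends"
  },
  "features": {
    "features": ["mav", "wl", "ssc", "zc"],
    "eps": 0
  },
  "motion_test": {
    "required_correct": 20,
    "timeout_s": 10,
    "window_ms": 200,
    "increment_ms": 50,
    "processing_latency_ms": 11,
    "trials_per_motion": 1,
    "n_tests": 2
  },
  "n_subjects": 6,
  "paired": true,
  "stats_m": 5,
  "seed": 1
}
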