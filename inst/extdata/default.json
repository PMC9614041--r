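{
  "pcm": {
    "N": 4,
    "k_m": 2.5,
    "d": 8,
    "e_pp": -60,
    "kBT": 4.14,
    "k01": 40,
    "k10": 2,
    "k20_0": 80,
    "f0_unbind": 12.6
  },
  "hill": {
    "f0_iso": 1000,
    "l_u": 0.2,
    "u0": 0.04,
    "alpha": 0,
    "fl_width": 0.45
  },
  "force_grid": [0, 2.5, 5, 7.5, 10, 12.5, 15, 17.5, 20, 22.5, 25, 27.5, 30, 32.5, 35, 37.5, 40, 42.5, 45, 47.5, 50, 52.5, 55, 57.5, 60],
  "method": "master_eq",
  "n_events": 20000,
  "seed": 1,
  "output_dir": "."
}
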