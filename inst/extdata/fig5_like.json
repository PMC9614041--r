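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
  "N_sweep": [4, 9, 15],
  "method": "master_eq",
  "seed": 1,
  "output_dir": "."
}
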