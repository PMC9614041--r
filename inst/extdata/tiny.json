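{
  "pcm": {
    "N": 2
  },
  "force_grid": [0, 5, 10, 15, 20],
  "method": "master_eq",
  "n_events": 2000,
  "seed": 1,
  "output_dir": "."
}
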