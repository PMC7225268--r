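{
  "species": "mouse",
  "tissue": {
    "young_modulus": 6000,
    "poisson_ratio": 0.43,
    "x_extent": 5000,
    "y_extent": 5000,
    "depth": 1250
  },
  "probe": {
    "young_modulus": 200000000000,
    "poisson_ratio": 0.27,
    "thickness": 15,
    "max_width": 123,
    "min_width": 33,
    "taper_length": 750,
    "tip_length": 50,
    "insertion_depth": 1000
  },
  "displacement": 20
}
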