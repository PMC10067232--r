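[
  {"x": 67.5, "y": 0.0,  "z": 0.0},
  {"x": 65.2, "y": 17.5, "z": 0.0},
  {"x": 58.5, "y": 33.8, "z": 0.0},
  {"x": 47.7, "y": 47.7, "z": 0.0},
  {"x": 33.8, "y": 58.5, "z": 0.0},
  {"x": 17.5, "y": 65.2, "z": 0.0},
  {"x": -0.1, "y": 67.4, "z": 0.2},
  {"x": -17.6, "y": 65.1, "z": 0.0}
]
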