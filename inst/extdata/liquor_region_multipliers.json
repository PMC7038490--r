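{
  "jiang": {
    "multipliers": [1.05, 1.50, 1.76, 2.24, 3.00],
    "words": ["Fully mellow", "Elegant and delicate", "Full bodied",
              "Long aftertaste", "Coordination"]
  },
  "feng": {
    "multipliers": [0.83, 1.30, 1.76, 2.24, 3.00],
    "words": ["Sweet and cool", "Long clean tail", "Mellow and elegant",
              "All tastes harmonize", "Mellow fullness"]
  },
  "nong": {
    "multipliers": [0.90, 1.39, 1.95, 2.24, 3.00],
    "words": ["Soft and sweet", "Sweet and refreshing", "Mellow",
              "Alcohol harmonious", "Long aftertaste"]
  },
  "mild": {
    "multipliers": [0.75, 1.21, 1.50, 1.95, 3.00],
    "words": ["Pure fragrance", "Long aftertaste", "Sweet and soft",
              "Natural coordination", "Sweet and refreshing"]
  }
}
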