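{
  "panel_size": 40,
  "jiang": {
    "words": ["Fully mellow", "Elegant and delicate", "Full bodied",
              "Long aftertaste", "Coordination"],
    "probabilities": [0.50, 0.25, 0.10, 0.10, 0.05],
    "counts": [20, 10, 4, 4, 2]
  },
  "feng": {
    "words": ["Sweet and cool", "Long clean tail", "Mellow and elegant",
              "All tastes harmonize", "Mellow fullness"],
    "probabilities": [0.35, 0.25, 0.20, 0.15, 0.05],
    "counts": null
  },
  "nong": {
    "words": ["Soft and sweet", "Sweet and refreshing", "Mellow",
              "Alcohol harmonious", "Long aftertaste"],
    "probabilities": [0.40, 0.25, 0.15, 0.10, 0.10],
    "counts": null
  },
  "mild": {
    "words": ["Pure fragrance", "Long aftertaste", "Sweet and soft",
              "Natural coordination", "Sweet and refreshing"],
    "probabilities": [0.30, 0.30, 0.20, 0.10, 0.10],
    "counts": null
  }
}
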