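{
  "jiang": ["Elegant and delicate", "Fully mellow", "Full bodied",
            "Long aftertaste", "Coordination"],
  "feng":  ["Mellow fullness", "Sweet and cool", "Mellow and elegant",
            "All tastes harmonize", "Long clean tail"],
  "nong":  ["Alcohol harmonious", "Sweet and refreshing", "Soft and sweet",
            "Long aftertaste", "Mellow"],
  "mild":  ["Pure fragrance", "Sweet and soft", "Natural coordination",
            "Sweet and refreshing", "Long aftertaste"]
}
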