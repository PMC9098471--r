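{
  "edition": "pilot",
  "levels": [
    {
      "name": "Mild",
      "n_images": 20,
      "classes": ["PT", "NT", "PNT", "NNT"],
      "class_mix": {"PT": 0.25, "NT": 0.58, "PNT": 0.10, "NNT": 0.07},
      "pass_threshold": 50
    },
    {
      "name": "Hot",
      "n_images": 30,
      "classes": ["PT", "NT", "PNT", "NNT"],
      "class_mix": {"PT": 0.23, "NT": 0.59, "PNT": 0.11, "NNT": 0.07},
      "pass_threshold": 50
    },
    {
      "name": "Spicy",
      "n_images": 50,
      "classes": ["PT", "NT", "PNT", "NNT"],
      "class_mix": {"PT": 0.21, "NT": 0.60, "PNT": 0.12, "NNT": 0.07},
      "pass_threshold": 50
    }
  ],
  "practice_levels": [
    {
      "name": "Practice",
      "n_images": 50,
      "classes": ["PT", "NT", "PNT", "NNT"],
      "class_mix": {"PT": 0.22, "NT": 0.59, "PNT": 0.12, "NNT": 0.07},
      "pass_threshold": 0
    }
  ]
}
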