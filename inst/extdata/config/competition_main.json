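{
  "edition": "main",
  "levels": [
    {
      "name": "Mild",
      "n_images": 20,
      "classes": ["PT"],
      "class_mix": {"PT": 1.0},
      "pass_threshold": 50
    },
    {
      "name": "Hot",
      "n_images": 40,
      "classes": ["PT", "NT"],
      "class_mix": {"PT": 0.35, "NT": 0.65},
      "pass_threshold": 50
    },
    {
      "name": "Spicy",
      "n_images": 60,
      "classes": ["PT", "NT", "PNT"],
      "class_mix": {"PT": 0.25, "NT": 0.62, "PNT": 0.13},
      "pass_threshold": 50
    },
    {
      "name": "Supercharger",
      "n_images": 80,
      "classes": ["PT", "NT", "PNT", "NNT"],
      "class_mix": {"PT": 0.21, "NT": 0.60, "PNT": 0.12, "NNT": 0.07},
      "pass_threshold": 50
    }
  ],
  "practice_levels": [
    {
      "name": "Mild",
      "n_images": 5,
      "classes": ["PT"],
      "class_mix": {"PT": 1.0},
      "pass_threshold": 0
    },
    {
      "name": "Hot",
      "n_images": 5,
      "classes": ["PT", "NT"],
      "class_mix": {"PT": 0.35, "NT": 0.65},
      "pass_threshold": 0
    }
  ]
}
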