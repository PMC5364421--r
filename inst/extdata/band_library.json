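[
  { "label": "cytoplasm",    "bands": [1008],        "tolerance": 8 },
  { "label": "nucleus",      "bands": [789],         "tolerance": 8 },
  { "label": "lipids",       "bands": [2857],        "tolerance": 8 },
  { "label": "glycogen",     "bands": [485],         "tolerance": 8 },
  { "label": "TAG",          "bands": [1747],        "tolerance": 8 },
  { "label": "cholesterol",  "bands": [1066, 1134],  "tolerance": 8 },
  { "label": "phospholipid", "bands": [719, 1085],   "tolerance": 8 },
  { "label": "PEG",          "bands": [847],         "tolerance": 8 },
  { "label": "medium",       "bands": [1640],        "tolerance": 8 }
]
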