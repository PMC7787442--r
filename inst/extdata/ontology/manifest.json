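[
  {
    "module": "consolidation",
    "n_classes": 0,
    "n_properties": 0,
    "n_defined": 0
  },
  {
    "module": "coordination",
    "n_classes": 7,
    "n_properties": 0,
    "n_defined": 0
  },
  {
    "module": "core",
    "n_classes": 19,
    "n_properties": 1,
    "n_defined": 7
  },
  {
    "module": "medical",
    "n_classes": 13,
    "n_properties": 0,
    "n_defined": 0
  },
  {
    "module": "socio-environnemental",
    "n_classes": 12,
    "n_properties": 0,
    "n_defined": 0
  },
  {
    "module": "total",
    "n_classes": 51,
    "n_properties": 1,
    "n_defined": 7
  }
]
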