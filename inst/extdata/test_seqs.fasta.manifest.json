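{
  "seed": 42,
  "spec": {
    "n_records": 5,
    "length_range": [500, 700],
    "gc_target": 50,
    "id_prefix": "demo",
    "n_planted": 0
  },
  "ids": ["demo_1", "demo_2", "demo_3", "demo_4", "demo_5"],
  "lengths": [548, 564, 652, 573, 645],
  "gc_realized": [53.2846715328467, 52.1276595744681, 51.840490797546, 45.7242582897033, 50.3875968992248],
  "total_length": 2982
}
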