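{
  "oxygen_exchange": "EX_o2_e",
  "R-H": {"nutrients": ["EX_glc__D_e", "EX_aux_e"], "uptake": 10, "oxygen": 20},
  "R-L": {"nutrients": ["EX_glc__D_e", "EX_aux_e"], "uptake": 10, "oxygen": 0.1},
  "M-H": {"nutrients": ["EX_glc__D_e"], "uptake": 10, "oxygen": 20},
  "M-L": {"nutrients": ["EX_glc__D_e"], "uptake": 10, "oxygen": 0.1}
}
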