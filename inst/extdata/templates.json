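{
  "templates": [
    {
      "name": "VMAP",
      "required": ["VMAP", "MoxR", "vWA"],
      "optional": ["Trypco1", "Trypco2", "ABhydrolase"],
      "anchor": "vWA",
      "effector_host": "vWA",
      "core_domain": "vWA",
      "max_gap": 70,
      "same_strand": true,
      "strict_order": true
    },
    {
      "name": "iSTAND",
      "required": ["MoxR", "vWA", "iSTAND"],
      "optional": [],
      "anchor": "vWA",
      "effector_host": "vWA",
      "core_domain": "vWA",
      "max_gap": 70,
      "same_strand": true,
      "strict_order": true
    },
    {
      "name": "FtsH",
      "required": ["MoxR", "vWA", "FtsH"],
      "optional": [],
      "anchor": "vWA",
      "effector_host": "vWA",
      "core_domain": "vWA",
      "max_gap": 70,
      "same_strand": true,
      "strict_order": true
    },
    {
      "name": "BetaPropeller",
      "required": ["MoxR", "vWA", "BetaPropeller"],
      "optional": [],
      "anchor": "vWA",
      "effector_host": "vWA",
      "core_domain": "vWA",
      "max_gap": 70,
      "same_strand": true,
      "strict_order": true
    },
    {
      "name": "GAP1-N1",
      "required": ["DO_GTPase", "GAP1_N1", "GASH"],
      "optional": ["DO_GTPase_paralog"],
      "anchor": "GAP1_N1",
      "effector_host": "GAP1_N1",
      "core_domain": "GAP1_N1",
      "max_gap": 70,
      "same_strand": true,
      "strict_order": true
    },
    {
      "name": "GAP1-N2",
      "required": ["DO_GTPase", "GAP1_N2", "FNIII"],
      "optional": [],
      "anchor": "GAP1_N2",
      "effector_host": "GAP1_N2",
      "core_domain": "GAP1_N2",
      "max_gap": 70,
      "same_strand": true,
      "strict_order": true
    },
    {
      "name": "NucA",
      "required": ["NucA", "Trypsin"],
      "optional": [],
      "anchor": "NucA",
      "effector_host": "NucA",
      "core_domain": "NucA",
      "max_gap": 70,
      "same_strand": true,
      "strict_order": true
    },
    {
      "name": "EACC1",
      "required": ["EACC1", "Caspase"],
      "optional": [],
      "anchor": "EACC1",
      "effector_host": "EACC1",
      "core_domain": "EACC1",
      "max_gap": 70,
      "same_strand": true,
      "strict_order": true
    }
  ]
}
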