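{
  "id": "toy6",
  "metabolites": [
    {"id": "a_e", "compartment": "e"},
    {"id": "a_c", "compartment": "c"},
    {"id": "b_c", "compartment": "c"}
  ],
  "reactions": [
    {
      "id": "EX_a_e",
      "metabolites": {"a_e": -1},
      "lower_bound": -10, "upper_bound": 1000,
      "gene_reaction_rule": "", "subsystem": "Exchange",
      "objective_coefficient": 0
    },
    {
      "id": "At",
      "metabolites": {"a_e": -1, "a_c": 1},
      "lower_bound": 0, "upper_bound": 1000,
      "gene_reaction_rule": "s0001", "subsystem": "Transport",
      "objective_coefficient": 0
    },
    {
      "id": "AB1",
      "metabolites": {"a_c": -1, "b_c": 1},
      "lower_bound": 0, "upper_bound": 1000,
      "gene_reaction_rule": "gA", "subsystem": "Glycolysis/Gluconeogenesis",
      "objective_coefficient": 0
    },
    {
      "id": "AB2",
      "metabolites": {"a_c": -1, "b_c": 1},
      "lower_bound": 0, "upper_bound": 1000,
      "gene_reaction_rule": "gB1 and gB2", "subsystem": "Glycolysis/Gluconeogenesis",
      "objective_coefficient": 0
    },
    {
      "id": "DM_a_c",
      "metabolites": {"a_c": -1},
      "lower_bound": 0, "upper_bound": 1000,
      "gene_reaction_rule": "", "subsystem": "Demand",
      "objective_coefficient": 0
    },
    {
      "id": "BIOMASS",
      "metabolites": {"b_c": -1},
      "lower_bound": 0, "upper_bound": 1000,
      "gene_reaction_rule": "", "subsystem": "Biomass",
      "objective_coefficient": 1
    }
  ],
  "genes": [
    {"id": "gA"}, {"id": "gB1"}, {"id": "gB2"}, {"id": "s0001"}
  ]
}
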