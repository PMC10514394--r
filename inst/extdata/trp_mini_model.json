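{
  "id": "compart_model",
  "version": "1",
  "metabolites": [
    {
      "id": "3ig3p_c",
      "name": "3ig3p_c",
      "notes": {
        "is_boundary": false
      }
    },
    {
      "id": "ser__L_c",
      "name": "ser__L_c",
      "notes": {
        "is_boundary": false
      }
    },
    {
      "id": "g3p_c",
      "name": "g3p_c",
      "notes": {
        "is_boundary": false
      }
    },
    {
      "id": "h2o_c",
      "name": "h2o_c",
      "notes": {
        "is_boundary": false
      }
    },
    {
      "id": "trp__L_c",
      "name": "trp__L_c",
      "notes": {
        "is_boundary": false
      }
    },
    {
      "id": "indole_c",
      "name": "indole_c",
      "notes": {
        "is_boundary": false
      }
    },
    {
      "id": "nh4_c",
      "name": "nh4_c",
      "notes": {
        "is_boundary": false
      }
    },
    {
      "id": "pyr_c",
      "name": "pyr_c",
      "notes": {
        "is_boundary": false
      }
    },
    {
      "id": "mtrp_c",
      "name": "mtrp_c",
      "notes": {
        "is_boundary": false
      }
    },
    {
      "id": "fald_c",
      "name": "fald_c",
      "notes": {
        "is_boundary": false
      }
    },
    {
      "id": "h2o2_c",
      "name": "h2o2_c",
      "notes": {
        "is_boundary": false
      }
    },
    {
      "id": "o2_c",
      "name": "o2_c",
      "notes": {
        "is_boundary": false
      }
    },
    {
      "id": "cit_c",
      "name": "cit_c",
      "notes": {
        "is_boundary": false
      }
    },
    {
      "id": "acon_C_c",
      "name": "acon_C_c",
      "notes": {
        "is_boundary": false
      }
    },
    {
      "id": "icit_c",
      "name": "icit_c",
      "notes": {
        "is_boundary": false
      }
    },
    {
      "id": "trp_e",
      "name": "trp_e",
      "notes": {
        "is_boundary": true
      }
    }
  ],
  "reactions": [
    {
      "id": "TRPS1",
      "name": "TRPS1",
      "metabolites": {
        "3ig3p_c": -1,
        "ser__L_c": -1,
        "g3p_c": 1,
        "h2o_c": 1,
        "trp__L_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "b1260 and b1261",
      "notes": {
        "status": "keep",
        "reversible": false
      }
    },
    {
      "id": "TRPS2",
      "name": "TRPS2",
      "metabolites": {
        "indole_c": -1,
        "ser__L_c": -1,
        "h2o_c": 1,
        "trp__L_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "b1260 and b1261",
      "notes": {
        "status": "keep",
        "reversible": false
      }
    },
    {
      "id": "TRPS3",
      "name": "TRPS3",
      "metabolites": {
        "3ig3p_c": -1,
        "g3p_c": 1,
        "indole_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "b1260 and b1261",
      "notes": {
        "status": "keep",
        "reversible": false
      }
    },
    {
      "id": "TRPAS2_reverse",
      "name": "TRPAS2_reverse",
      "metabolites": {
        "indole_c": -1,
        "nh4_c": -1,
        "pyr_c": -1,
        "h2o_c": 1,
        "trp__L_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "b3708",
      "notes": {
        "status": "keep",
        "reversible": false
      }
    },
    {
      "id": "MTRPOXN",
      "name": "MTRPOXN",
      "metabolites": {
        "mtrp_c": -1,
        "h2o_c": -1,
        "o2_c": -1,
        "fald_c": 1,
        "h2o2_c": 1,
        "trp__L_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "b1059",
      "notes": {
        "status": "keep",
        "reversible": false
      }
    },
    {
      "id": "ACONTa",
      "name": "ACONTa",
      "metabolites": {
        "cit_c": -1,
        "acon_C_c": 1,
        "h2o_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "b0118 and b1276",
      "notes": {
        "status": "keep",
        "reversible": false
      }
    },
    {
      "id": "ACONTb",
      "name": "ACONTb",
      "metabolites": {
        "acon_C_c": -1,
        "h2o_c": -1,
        "icit_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "b0118 and b1276",
      "notes": {
        "status": "keep",
        "reversible": false
      }
    },
    {
      "id": "ACONTa_r",
      "name": "ACONTa_r",
      "metabolites": {
        "acon_C_c": -1,
        "h2o_c": -1,
        "cit_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "b0118 and b1276",
      "notes": {
        "status": "keep",
        "reversible": false
      }
    },
    {
      "id": "ACONTb_r",
      "name": "ACONTb_r",
      "metabolites": {
        "icit_c": -1,
        "acon_C_c": 1,
        "h2o_c": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "b0118 and b1276",
      "notes": {
        "status": "keep",
        "reversible": false
      }
    },
    {
      "id": "EX_trp",
      "name": "EX_trp",
      "metabolites": {
        "trp__L_c": -1,
        "trp_e": 1
      },
      "lower_bound": 0,
      "upper_bound": 1000,
      "gene_reaction_rule": "",
      "notes": {
        "status": "keep",
        "reversible": false
      }
    }
  ],
  "notes": {
    "total_enzyme_bound": 0.13,
    "provenance": "miniature tryptophan-synthesis reaction set",
    "exchanges": [
      "EX_trp"
    ]
  }
}
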