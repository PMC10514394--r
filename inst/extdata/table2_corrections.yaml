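# Corrections to the tryptophan-synthesis reaction set: keep the overall
# tryptophan-synthase reaction (TRPS1), shut its partial reactions (the
# indole intermediate travels through a channel inside the enzyme), and
# merge the two aconitase half-reactions (the cis-aconitate intermediate
# does not leave the active site) into a reversible overall pair.
merges:
  - merged_id: ACONT
    parts:
      - reaction: ACONTa
        multiplier: 1
      - reaction: ACONTb
        multiplier: 1
    declared_intermediates: [acon_C_c, h2o_c]
    dG0_override: 8.3
    reversible_pair: true
shut: [TRPS2, TRPS3, ACONTa_r, ACONTb_r]
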