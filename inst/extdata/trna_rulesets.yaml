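# Identity-element rulesets: per isotype, `required` elements must all be
# satisfied; `support` elements are reported but never required.
# Element syntax: allowed bases ("A", "A/G"), negation ("!A"), ordered base
# pairs ("G:C"), "weak" for a non-G:C/C:G 1:72 pair, ">12" for the
# variable-loop length. Positions use standard tRNA numbering.
bacterial_arg_met:
  Arg:
    required: {n20: A, n73: A/G}
  Met:
    required: {n73: A, n20: "!A"}
    support: {n2_71: "G:C", n3_70: "C:G"}
bacterial_trp:
  Trp:
    required: {n73: G, n20: "!A"}
    support: {n1_72: "A:U/G:U"}
bacterial_gln:
  Gln:
    required: {n1_72: weak, n37: A, n73: A/G, n20: "!A"}
    support: {n2_71: "G:C", n3_70: "G:C", n38: G, n10: G}
bacterial_gly:
  Gly:
    required: {n1_72: "G:C", n2_71: "C:G", n3_70: "G:C", n73: U}
yeast_ser_leu:
  Leu:
    required: {var_loop_len: ">12", n73: A, n35: A, n37: G}
  Ser:
    required: {var_loop_len: ">12"}
    flag_if_not: {n73: G}
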