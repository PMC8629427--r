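# canonical 76-nt cloverleaf used by the parsing tests; the D-loop and
# discriminator base are swapped per variant
trna_fixture <- function(d_loop = "AGUUGGCC", n73 = "A",
                         ac_loop = "CUCCUAA", var_loop = "AGGUC") {
  seq <- paste0(
    "GGCAAGG", "UA", "GCGC", d_loop, "GCGC", "A",
    "GGGGG", ac_loop, "CCCCC", var_loop,
    "GGUUC", "UUCGAUU", "GAACC", "CCUUGCC", n73, "CCA")
  structure_str <- paste0(
    strrep(">", 7), "..", strrep(">", 4), strrep(".", nchar(d_loop)),
    strrep("<", 4), ".",
    strrep(">", 5), ".......", strrep("<", 5),
    strrep(".", nchar(var_loop)),
    strrep(">", 5), ".......", strrep("<", 5), strrep("<", 7), ".", "...")
  list(seq = seq, structure = structure_str)
}

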