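# Brute-force oracle for the codon decoding posterior: evaluates the
# generative model literally, in plain (non-log) arithmetic, keeping the
# column-draw factors P(Ci) = 1/pool_size explicit for every model instead
# of cancelling them. Independent of the log-space implementation it checks.
oracle_posterior <- function(E, counts, bg, pool_size = 1000) {
  pc <- 1 / pool_size
  lik_aa <- vapply(seq_len(20), function(a) {
    prod((E[, a] * pc / bg[a])^counts)
  }, numeric(1))
  lik_q <- prod(pc^counts)
  lik <- c(lik_aa, lik_q)
  lik / sum(lik)
}

# a profile_db wrapping a bare emission matrix as one synthetic domain
toy_db <- function(E, acc = "TOY") {
  E <- t(apply(E, 1, function(p) pmax(p, 1e-6) / sum(pmax(p, 1e-6))))
  codonscope:::new_profile_db(
    tibble::tibble(acc = acc, name = acc, length = nrow(E)),
    E, rep(acc, nrow(E)), seq_len(nrow(E)))
}

# association-set column tibble for a toy_db
toy_cols <- function(col_index, count = 1L, acc = "TOY") {
  tibble::tibble(acc = acc, col_index = as.integer(col_index),
                 count = as.integer(count))
}

# emission row concentrated on one amino acid (before clamping)
unit_emission <- function(aa_letter) {
  e <- rep(0, 20)
  e[match(aa_letter, amino_acids())] <- 1
  e
}

# minimal aligned-pair tibble with sensible defaults
mk_pairs <- function(codon, acc = "TOY", col_index = 1L, evalue = 1e-20,
                     pp = "*", name = acc, start = 0L, strand = "+",
                     record_id = "r") {
  tibble::tibble(codon = codon, acc = acc, name = name,
                 col_index = as.integer(col_index), evalue = evalue,
                 evalue_cond = evalue, pp = pp, record_id = record_id,
                 start = as.integer(start), strand = strand)
}
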