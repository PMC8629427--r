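Package: codonscope
Title: Genetic Code Inference from Nucleotide Sequence via Profile Consensus Columns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the amino acid translation of each of the 64 codons for a
    single organism directly from nucleotide sequence. A six-frame standard-code
    translation is aligned to a database of conserved protein-domain profiles;
    every aligned profile consensus column carries a 20-way amino acid emission
    distribution, and a Bayesian model comparison over 21 decoding hypotheses
    (20 amino acids plus a nonspecific model) yields a posterior decoding
    probability per codon. Includes a synthetic-data generator emulating domain
    profiles and genomes under arbitrary genetic codes, a subsampling
    error/power benchmark, parsers for HMMER3 profile and hmmscan alignment
    output, and a rule-based tRNA isotype classifier using identity elements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
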