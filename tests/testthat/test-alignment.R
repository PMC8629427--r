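test_that("hmmscan output parsing recovers match columns, skips inserts", {
  hits <- parse_search_output(test_path("fixtures", "hmmscan_mini.txt"))
  a <- hits[hits$target == "DOMA", ]
  # 9 alignment columns: 1 insert (x over '.') and 1 deletion drop out
  expect_equal(nrow(a), 7L)
  expect_equal(a$qpos, c(5L, 6L, 7L, 8L, 10L, 11L, 12L))
  expect_equal(a$col_index, c(3L, 4L, 5L, 6L, 7L, 8L, 10L))
  expect_equal(a$pp, c("8", "9", "9", "9", "9", "*", "9"))
  expect_equal(unique(a$evalue), 1e-15)
  expect_equal(unique(a$evalue_cond), 2e-20)
  b <- hits[hits$target == "DOMB", ]
  expect_equal(nrow(b), 4L)
  expect_equal(unique(b$evalue), 5e-9)
})

test_that("pp code line character i annotates aligned pair i", {
  hits <- parse_search_output(test_path("fixtures", "hmmscan_mini.txt"))
  b <- hits[hits$target == "DOMB", ]
  expect_equal(b$pp, c("9", "*", "*", "*"))
})

test_that("posterior-code bins: only '*' passes at pp_min 0.95", {
  pairs <- mk_pairs(codon = rep("TGA", 3), pp = c("9", "*", "8"))
  kept <- filter_pairs(pairs, pp_min = 0.95)
  expect_equal(kept$pp, "*")
  # at 0.85, the '9' bin (0.85, 0.95] also passes
  kept85 <- filter_pairs(pairs, pp_min = 0.85)
  expect_setequal(kept85$pp, c("9", "*"))
})

test_that("E-value threshold is a strict inequality at 1e-10", {
  pairs <- mk_pairs(codon = rep("ATG", 3), evalue = c(1e-9, 1e-10, 1e-11))
  kept <- filter_pairs(pairs)
  expect_equal(kept$evalue, 1e-11)
})

test_that("excluded accessions are dropped regardless of scores", {
  pairs <- mk_pairs(codon = c("ATG", "ATG"), acc = c("PF1", "BAD1"),
                    name = c("DomOne", "Transposase_21"))
  kept <- filter_pairs(pairs, excluded = c("Transposase*"))
  expect_equal(kept$acc, "PF1")
  kept2 <- filter_pairs(pairs, excluded = c("BAD1"))
  expect_equal(kept2$acc, "PF1")
})

test_that("filter_pairs is a pure, idempotent filter", {
  set.seed(11)
  pairs <- mk_pairs(codon = sample(codons(), 50, replace = TRUE),
                    evalue = 10^-sample(5:20, 50, replace = TRUE),
                    pp = sample(c("7", "8", "9", "*"), 50, replace = TRUE))
  once <- filter_pairs(pairs)
  twice <- filter_pairs(once)
  expect_identical(once, twice)
  expect_true(all(vapply(seq_len(nrow(once)), function(i) {
    any(pairs$evalue == once$evalue[i] & pairs$codon == once$codon[i])
  }, TRUE)))
})

test_that("pairs map back to genomic codons on both strands", {
  recs <- tibble::tibble(id = "chr", seq = "AAATGTTTGGGC",
                         source_offset = 0L)
  tr <- six_frame_translate(recs)
  # frame 2, peptide position 1 -> codon at nt 5..7 on '+'
  hits <- tibble::tibble(query = "chr|chunk1|frame2", target = "TOY",
                         domain_idx = 1L, evalue = 1e-20, evalue_cond = 1e-20,
                         qpos = 2L, col_index = 4L, pp = "*")
  p <- pairs_from_hits(hits, tr, recs)
  expect_equal(p$start, 5L)
  expect_equal(p$codon, substr(recs$seq, 6, 8))
  # reverse frame: codon re-derives by revcomp
  hits_r <- tibble::tibble(query = "chr|chunk1|frame3", target = "TOY",
                           domain_idx = 1L, evalue = 1e-20,
                           evalue_cond = 1e-20, qpos = 1L, col_index = 1L,
                           pp = "*")
  pr <- pairs_from_hits(hits_r, tr, recs)
  fwd <- substr(recs$seq, pr$start + 1, pr$start + 3)
  expect_equal(codonscope:::revcomp(fwd), pr$codon)
  expect_equal(pr$strand, "-")
  expect_error(
    pairs_from_hits(dplyr::mutate(hits, query = "nope|chunk1|frame0"),
                    tr, recs),
    "unknown query")
})

test_that("pairs over ambiguity-code codons are dropped, stop codons kept", {
  recs <- tibble::tibble(id = "chr", seq = "ATGANTTGATGG",
                         source_offset = 0L)
  tr <- six_frame_translate(recs)
  hits <- tibble::tibble(query = rep("chr|chunk1|frame0", 3), target = "TOY",
                         domain_idx = 1L, evalue = 1e-20, evalue_cond = 1e-20,
                         qpos = 1:3, col_index = 1:3, pp = "*")
  p <- pairs_from_hits(hits, tr, recs)
  # codon 2 (ANT) dropped; codon 3 is the in-frame TGA stop, retained
  expect_equal(p$codon, c("ATG", "TGA"))
})

test_that("the real search backend reproduces emulated associations", {
  # synthetic domains -> seed alignments -> hmmbuild --enone -> hmmscan;
  # the parsed pairs must round-trip to the ground-truth columns
  wd <- tempfile("hmmwork")
  dir.create(wd)
  set.seed(21)
  cfg <- sim_config(n_domains = 2, cols_per_domain = 35, strong_mean = 0.8,
                    strong_conc = 80, weak_frac = 0.1, n_genes = 12,
                    seed = 21)
  db_syn <- make_profiles(cfg)
  aa <- amino_acids()
  hmms <- character(2)
  for (d in 1:2) {
    rows <- which(db_syn$acc == db_syn$domains$acc[d])
    E <- db_syn$emissions[rows, ]
    seqs <- vapply(1:30, function(i) {
      paste(aa[codonscope:::sample_aa_from_emissions(E)], collapse = "")
    }, "")
    sto <- file.path(wd, sprintf("d%d.sto", d))
    writeLines(c("# STOCKHOLM 1.0",
                 sprintf("s%02d  %s", 1:30, seqs), "//"), sto)
    hmms[d] <- file.path(wd, sprintf("d%d.hmm", d))
    st <- system2("hmmbuild",
                  c("--enone", "-n", db_syn$domains$name[d], hmms[d], sto),
                  stdout = FALSE, stderr = FALSE)
    expect_equal(st, 0L)
  }
  dbfile <- file.path(wd, "db.hmm")
  file.create(dbfile)
  file.append(dbfile, hmms)
  db <- parse_profile_db(dbfile)
  sim <- make_genome(sim_config(n_domains = 2, cols_per_domain = 35,
                                n_genes = 12, seed = 22), db)
  fa <- file.path(wd, "genome.fa")
  write_fasta(sim$seqs, fa)
  recs <- read_fasta(fa)
  tr <- six_frame_translate(chunk_sequence(recs))
  pep <- file.path(wd, "sixframe.faa")
  write_translations(tr, pep)
  out <- run_search(pep, dbfile, workdir = wd)
  hits <- parse_search_output(out)
  expect_gt(nrow(hits), 300)
  pairs <- pairs_from_hits(hits, tr, recs, db = db)
  # every pair's codon re-derives from the genome
  fwd <- codonscope:::codons_at(recs$seq[1], pairs$start)
  chk <- ifelse(pairs$strand == "+", fwd, codonscope:::revcomp(fwd))
  expect_true(all(chk == pairs$codon))
  # aligned columns agree with the generative ground truth
  m <- dplyr::inner_join(pairs, sim$truth, by = c("start", "strand"),
                         suffix = c("", ".true"))
  expect_gt(nrow(m), 300)
  expect_gt(mean(m$acc == m$acc.true & m$col_index == m$col_index.true),
            0.97)
})

test_that("an empty peptide FASTA yields an empty hit set without error", {
  wd <- tempfile("empty")
  dir.create(wd)
  pep <- file.path(wd, "none.faa")
  writeLines(character(0), pep)
  out <- run_search(pep, "unused.hmm", workdir = wd)
  expect_equal(nrow(parse_search_output(out)), 0L)
})
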