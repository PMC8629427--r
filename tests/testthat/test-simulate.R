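test_that("profile generation is reproducible and respects conservation", {
  cfg <- sim_config(n_domains = 5, cols_per_domain = 60, seed = 41)
  db1 <- make_profiles(cfg)
  db2 <- make_profiles(cfg)
  expect_identical(db1$emissions, db2$emissions)
  expect_identical(db1$designated, db2$designated)
  # with high conservation the argmax recovers the designated amino acid
  hi <- sim_config(n_domains = 10, cols_per_domain = 100, strong_mean = 0.9,
                   strong_conc = 100, weak_frac = 0, seed = 42)
  dbh <- make_profiles(hi)
  arg <- amino_acids()[max.col(dbh$emissions)]
  expect_gte(mean(arg == dbh$designated$aa), 0.95)
  # strong columns average near the configured conservation level
  strong_rows <- which(dbh$designated$strong)
  top <- dbh$emissions[cbind(strong_rows,
                             match(dbh$designated$aa[strong_rows],
                                   amino_acids()))]
  expect_equal(mean(top), 0.9, tolerance = 0.02)
})

test_that("zero domains yield an empty database and an all-'?' code", {
  cfg <- sim_config(n_domains = 0, cols_per_domain = 0, seed = 43)
  db <- make_profiles(cfg)
  expect_equal(nrow(db$emissions), 0L)
  fit <- suppressWarnings(infer_genetic_code(mk_pairs(character(0)), db))
  expect_true(all(fit$aa == "?"))
})

test_that("gene codon frequencies follow the configured usage", {
  usage <- stats::setNames(rep(1, 64), codons())
  usage[standard_code() == "*"] <- 0
  usage["CTG"] <- 4   # leucine skewed toward CTG
  cfg <- sim_config(n_domains = 10, cols_per_domain = 125, n_genes = 400,
                    codon_usage = usage, seed = 44)
  db <- make_profiles(cfg)
  sim <- make_genome(cfg, db)   # 50,000 coding codons
  expect_gte(nrow(sim$truth), 50000)
  leu <- sim$truth[sim$truth$aa == "L", ]
  tab <- table(factor(leu$codon, levels = codonscope:::codons_for("L")))
  want <- usage[names(tab)] / sum(usage[names(tab)])
  chi <- stats::chisq.test(tab, p = want)
  expect_gt(chi$p.value, 1e-4)
  # overall per-amino-acid codon split is uniform where usage is uniform
  gly <- sim$truth[sim$truth$aa == "G", ]
  gtab <- table(factor(gly$codon, levels = codonscope:::codons_for("G")))
  gchi <- stats::chisq.test(gtab, p = rep(1 / 4, 4))
  expect_gt(gchi$p.value, 1e-4)
})

test_that("ground-truth codons re-derive from the genome on both strands", {
  cfg <- sim_config(n_domains = 4, cols_per_domain = 40, n_genes = 30,
                    seed = 45)
  db <- make_profiles(cfg)
  sim <- make_genome(cfg, db)
  fwd <- codonscope:::codons_at(sim$seqs$seq, sim$truth$start)
  cdn <- ifelse(sim$truth$strand == "+", fwd, codonscope:::revcomp(fwd))
  expect_true(all(cdn == sim$truth$codon))
  expect_setequal(unique(sim$truth$strand), c("+", "-"))
})

test_that("under a CUG->Ser code, CTG appears only at serine positions", {
  cfg <- sim_config(code = code_with(CTG = "S"), n_domains = 6,
                    cols_per_domain = 80, n_genes = 60, seed = 46)
  db <- make_profiles(cfg)
  sim <- make_genome(cfg, db)
  ctg <- sim$truth[sim$truth$codon == "CTG", ]
  expect_gt(nrow(ctg), 0)
  expect_true(all(ctg$aa == "S"))
})

test_that("stop codons never appear inside genes", {
  cfg <- sim_config(n_domains = 5, cols_per_domain = 60, n_genes = 50,
                    seed = 47)
  db <- make_profiles(cfg)
  sim <- make_genome(cfg, db)
  stops <- names(standard_code())[standard_code() == "*"]
  expect_false(any(sim$truth$codon %in% stops))
  assoc <- build_association_sets(
    filter_pairs(emulate_associations(sim$truth, db)))
  expect_true(all(assoc$n_total[assoc$codon %in% stops] == 0L))
})

test_that("an amino acid with zero codon weight under the code errors", {
  usage <- stats::setNames(rep(1, 64), codons())
  usage[codonscope:::codons_for("W")] <- 0   # tryptophan unencodable
  cfg <- sim_config(n_domains = 6, cols_per_domain = 80, n_genes = 20,
                    codon_usage = usage, seed = 48)
  db <- make_profiles(cfg)
  expect_error(make_genome(cfg, db), "zero total codon weight")
})

test_that("emulated associations reproduce truth and corrupt at rate noise", {
  cfg <- sim_config(n_domains = 5, cols_per_domain = 60, n_genes = 60,
                    seed = 49)
  db <- make_profiles(cfg)
  sim <- make_genome(cfg, db)
  clean <- emulate_associations(sim$truth, db, noise = 0)
  expect_equal(clean$acc, sim$truth$acc)
  expect_equal(clean$col_index, sim$truth$col_index)
  expect_true(all(clean$pp == "*"))
  expect_true(all(clean$evalue < 1e-10))
  noisy <- emulate_associations(sim$truth, db, noise = 0.05, seed = 49)
  frac <- mean(noisy$acc != sim$truth$acc |
                 noisy$col_index != sim$truth$col_index)
  n <- nrow(sim$truth)
  expect_lt(abs(frac - 0.05), 4 * sqrt(0.05 * 0.95 / n) + 0.003)
  # reproducible from the seed
  noisy2 <- emulate_associations(sim$truth, db, noise = 0.05, seed = 49)
  expect_identical(noisy, noisy2)
})

test_that("corruption degrades the true model's posterior on average", {
  cfg <- sim_config(n_domains = 8, cols_per_domain = 60, n_genes = 80,
                    seed = 50)
  db <- make_profiles(cfg)
  sim <- make_genome(cfg, db)
  truth_aa <- standard_code()
  mean_post <- function(noise) {
    pairs <- emulate_associations(sim$truth, db, noise = noise, seed = 50)
    fit <- infer_genetic_code(pairs, db)
    posts <- attr(fit, "posteriors")
    used <- which(fit$n_columns > 0)
    mean(vapply(used, function(i) {
      dp <- posts[[i]]
      dp$posterior[dp$model == truth_aa[[fit$codon[i]]]]
    }, numeric(1)))
  }
  p0 <- mean_post(0)
  p3 <- mean_post(0.3)
  p6 <- mean_post(0.6)
  expect_gte(p0, p3)
  expect_gte(p3, p6)
})

test_that("subsample accounting is exact and a zero size is all-'?'", {
  pools <- make_codon_pools(n_per_codon = 150, seed = 51,
                            code = code_with(
                              code = stats::setNames(rep("*", 64), codons()),
                              TGG = "W", ATG = "M", AAA = "K"))
  ep <- subsample_experiment(pools, sizes = c(0L, 2L, 10L), n_reps = 200,
                             seed = 51)
  expect_true(all(ep$n_true + ep$n_false + ep$n_uninferred == ep$n_reps))
  expect_equal(ep$error_rate, ep$n_false / ep$n_reps)
  expect_equal(ep$power, ep$n_true / ep$n_reps)
  z <- ep[ep$set_size == 0, ]
  expect_true(all(z$power == 0 & z$error_rate == 0))
})

test_that("perfectly conserved ratio-20 pools reach power 1 at size 4", {
  # emission 1 on the true amino acid, uniform background 0.05: each
  # column contributes a likelihood ratio of 20, and 20^4/(20^4+1) > 0.9999
  code <- stats::setNames(rep("*", 64), codons())
  code[c("TGG", "ATG")] <- c("W", "M")
  pools <- structure(
    list(TGG = do.call(rbind, replicate(50, unit_emission("W"),
                                        simplify = FALSE)),
         ATG = do.call(rbind, replicate(50, unit_emission("M"),
                                        simplify = FALSE))),
    class = "codon_pools", truth = c(TGG = "W", ATG = "M"))
  pools <- lapply(pools, function(E)
    t(apply(E, 1, function(p) pmax(p, 1e-6) / sum(pmax(p, 1e-6)))))
  pools <- structure(pools, class = "codon_pools",
                     truth = c(TGG = "W", ATG = "M"))
  ep <- subsample_experiment(pools, sizes = c(3L, 4L), n_reps = 100,
                             bg = rep(0.05, 20), seed = 52)
  expect_true(all(ep$power[ep$set_size == 4] == 1))
  expect_true(all(ep$power[ep$set_size == 3] == 0))
  expect_true(all(ep$error_rate == 0))
})

test_that("the vectorized benchmark matches decoding_posterior per sample", {
  set.seed(53)
  E <- matrix(stats::rgamma(8 * 20, shape = 1), 8, 20)
  E <- t(apply(E, 1, function(p) pmax(p / sum(p), 1e-6)))
  E <- E / rowSums(E)
  pools <- structure(list(AAA = E), class = "codon_pools",
                     truth = c(AAA = "K"))
  bg <- rep(0.05, 20)
  ep <- subsample_experiment(pools, sizes = 3L, n_reps = 50, bg = bg,
                             seed = 53, threshold = 0.8)
  # replay the same draws through the reference per-codon path
  db <- toy_db(E)
  codonscope:::with_seed(codonscope:::sub_seed(53, "subsampling"), {
    idx <- sample.int(8, 3 * 50, replace = TRUE)
  })
  grp <- rep(seq_len(50), each = 3)
  calls <- vapply(split(idx, grp), function(ix) {
    tab <- table(ix)
    cols <- toy_cols(as.integer(names(tab)), as.integer(tab))
    assign_codon(decoding_posterior(cols, db, bg), threshold = 0.8)
  }, "")
  expect_equal(sum(calls == "K"), ep$n_true)
  expect_equal(sum(!calls %in% c("K", "?")), ep$n_false)
})

test_that("power is non-decreasing in subsample size on conserved pools", {
  pools <- make_codon_pools(n_per_codon = 400, seed = 54)
  pools <- structure(pools[c("TGG", "ATG", "AAA", "GAA")],
                     class = "codon_pools",
                     truth = attr(pools, "truth")[c("TGG", "ATG", "AAA",
                                                    "GAA")])
  ep <- subsample_experiment(pools, sizes = c(5L, 15L, 40L), n_reps = 400,
                             seed = 54)
  for (z in unique(ep$codon)) {
    pw <- ep$power[ep$codon == z][order(ep$set_size[ep$codon == z])]
    expect_true(all(diff(pw) >= -0.05))   # Monte-Carlo tolerance
  }
})

test_that("pools built from association sets expand occurrence counts", {
  cfg <- sim_config(n_domains = 4, cols_per_domain = 50, n_genes = 40,
                    seed = 55)
  db <- make_profiles(cfg)
  sim <- make_genome(cfg, db)
  assoc <- downsample_associations(build_association_sets(
    filter_pairs(emulate_associations(sim$truth, db))))
  truth <- cfg$code[cfg$code %in% amino_acids()]
  pools <- pools_from_associations(assoc, db, truth, min_pool = 10L)
  expect_gt(length(pools), 30)
  z <- names(pools)[1]
  expect_equal(nrow(pools[[z]]), assoc$n_total[assoc$codon == z])
})
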