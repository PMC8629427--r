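#' @title Synthetic data: profiles, genomes and emulated alignments
#' @description The generator emulates the statistical structure the
#'   decoder assumes: domain profiles whose consensus columns are Dirichlet
#'   draws mixing strong conservation for a designated amino acid with a
#'   weakly conserved admixture; genomes whose genes are paths through those
#'   columns, each column emitting an amino acid that is then encoded as a
#'   codon under an arbitrary ground-truth genetic code and codon-usage
#'   table; and an alignment emulator that replays the ground-truth
#'   codon-column pairs (optionally corrupted) so the whole pipeline runs
#'   with no external search program.
#' @name simulate
NULL

# run expr with a temporary RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# named substream seed derived from a run seed, kept below 2^31
sub_seed <- function(seed, what) {
  (abs(seed) + sum(utf8ToInt(what)) * 10007L) %% 2147483587L
}

# n Dirichlet draws with concentration vector alpha, as an n x 20 matrix
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = rep(alpha, each = n)),
              nrow = n)
  g / rowSums(g)
}

# emission rows for `aa_idx` designated amino acids: strong Dirichlet
# (mean `strong_mean` on the designated letter) vs weak symmetric Dirichlet
sim_emission_rows <- function(aa_idx, strong, strong_mean, strong_conc,
                              weak_conc) {
  n <- length(aa_idx)
  E <- matrix(0, n, 20)
  if (any(!strong)) {
    E[!strong, ] <- rdirichlet(sum(!strong), rep(weak_conc, 20))
  }
  if (any(strong)) {
    rest <- (1 - strong_mean) / 19 * strong_conc
    for (a in unique(aa_idx[strong])) {
      rows <- which(strong & aa_idx == a)
      alpha <- rep(rest, 20)
      alpha[a] <- strong_mean * strong_conc
      E[rows, ] <- rdirichlet(length(rows), alpha)
    }
  }
  t(apply(E, 1, clamp_renorm))
}

#' Simulation configuration
#'
#' Bundles the study conditions for the synthetic generator. Defaults give
#' 200 genes of 200 codons (40,000 coding codons) emitted through 25
#' domains of 200 consensus columns each, with consensus conservation of
#' mean 0.6 on the designated amino acid, a 20 percent weakly conserved
#' admixture, uniform codon usage among synonymous codons, and an AT-rich
#' intergenic background.
#'
#' @param n_domains Number of synthetic domains.
#' @param cols_per_domain Consensus columns per domain.
#' @param strong_mean Mean emission of a strongly conserved column on its
#'   designated amino acid.
#' @param strong_conc Dirichlet concentration (total mass) of strong
#'   columns; larger is less variable.
#' @param weak_frac Fraction of weakly conserved columns.
#' @param weak_conc Symmetric Dirichlet concentration of weak columns.
#' @param code Ground-truth genetic code (see [standard_code()]); must map
#'   every codon to an amino acid or `"*"`.
#' @param n_genes Number of genes in the synthetic genome.
#' @param codon_usage Named 64-vector of non-negative relative weights;
#'   stop codons are forced to 0. Default: uniform over sense codons.
#' @param gc_bias GC fraction of intergenic sequence.
#' @param intergenic_len Mean intergenic length (nt, Poisson).
#' @param seed Run seed; all substreams derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_domains = 25L, cols_per_domain = 200L,
                       strong_mean = 0.6, strong_conc = 50,
                       weak_frac = 0.2, weak_conc = 1,
                       code = standard_code(), n_genes = 200L,
                       codon_usage = NULL, gc_bias = 0.35,
                       intergenic_len = 60, seed = 2063L) {
  if (is.null(codon_usage)) {
    codon_usage <- stats::setNames(as.numeric(code != "*" & code != "?"),
                                   names(code))
  }
  codon_usage[code == "*"] <- 0
  stopifnot(all(codon_usage >= 0), length(codon_usage) == 64)
  structure(list(n_domains = n_domains, cols_per_domain = cols_per_domain,
                 strong_mean = strong_mean, strong_conc = strong_conc,
                 weak_frac = weak_frac, weak_conc = weak_conc, code = code,
                 n_genes = n_genes, codon_usage = codon_usage,
                 gc_bias = gc_bias, intergenic_len = intergenic_len,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a synthetic profile database
#'
#' Each consensus column receives a designated amino acid (uniform over the
#' 20) and an emission vector drawn from a mixture of a strongly conserved
#' Dirichlet centered on that amino acid and a weak symmetric Dirichlet.
#' Reproducible from the config seed; [write_profile_db()] serializes the
#' result in the format [parse_profile_db()] reads.
#'
#' @param cfg A [sim_config()].
#' @return A `profile_db` with an extra `designated` element: a tibble
#'   (`acc`, `col_index`, `aa`, `strong`) recording the ground truth per
#'   column.
#' @export
make_profiles <- function(cfg) {
  with_seed(sub_seed(cfg$seed, "profiles"), {
    aa <- amino_acids()
    L <- cfg$cols_per_domain
    total <- cfg$n_domains * L
    if (total == 0) {
      db <- new_profile_db(
        tibble::tibble(acc = character(), name = character(),
                       length = integer()),
        matrix(0, 0, 20), character(), integer())
      db$designated <- tibble::tibble(acc = character(),
                                      col_index = integer(),
                                      aa = character(), strong = logical())
      return(db)
    }
    acc <- rep(sprintf("SYN%05d", seq_len(cfg$n_domains)), each = L)
    col_index <- rep(seq_len(L), cfg$n_domains)
    aa_idx <- sample.int(20, total, replace = TRUE)
    strong <- stats::runif(total) >= cfg$weak_frac
    E <- sim_emission_rows(aa_idx, strong, cfg$strong_mean, cfg$strong_conc,
                           cfg$weak_conc)
    domains <- tibble::tibble(acc = sprintf("SYN%05d", seq_len(cfg$n_domains)),
                              name = sprintf("synDom%d", seq_len(cfg$n_domains)),
                              length = as.integer(L))
    db <- new_profile_db(domains, E, acc, col_index)
    db$designated <- tibble::tibble(acc = acc, col_index = col_index,
                                    aa = aa[aa_idx], strong = strong)
    db
  })
}

# sample one amino acid index per row of an emission matrix
sample_aa_from_emissions <- function(E) {
  cum <- t(apply(E, 1, cumsum))
  u <- stats::runif(nrow(E))
  as.integer(rowSums(u > cum) + 1L)
}

# random intergenic DNA with a given GC fraction
random_dna <- function(n, gc) {
  if (n <= 0) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic genome with ground-truth codon-column pairs
#'
#' Genes are sampled paths through the columns of a randomly chosen domain;
#' each column emits an amino acid from its emission vector, which is then
#' encoded as a codon drawn from the configured codon usage restricted to
#' that amino acid under the ground-truth code. Genes alternate strands and
#' are separated by random intergenic sequence. Stop codons never occur
#' inside genes (their usage weight is zero), so their association sets are
#' empty end to end.
#'
#' @param cfg A [sim_config()].
#' @param db A `profile_db` from [make_profiles()].
#' @return A list of class `sim_genome`: `seqs` (single-record sequence
#'   tibble), `truth` (aligned-pair ground truth: `record_id`, `start`,
#'   `strand`, `codon`, `acc`, `col_index`, `aa`), `config`.
#' @export
make_genome <- function(cfg, db) {
  with_seed(sub_seed(cfg$seed, "genome"), {
    aa <- amino_acids()
    code <- cfg$code
    usage <- cfg$codon_usage
    # per amino acid: codons and weights available under the code
    enc <- lapply(aa, function(a) {
      cs <- codons_for(a, code)
      w <- usage[cs]
      cs <- cs[w > 0]
      list(codons = cs, w = usage[cs])
    })
    names(enc) <- aa
    domain_of <- sample.int(nrow(db$domains), cfg$n_genes, replace = TRUE)
    pieces <- character(2 * cfg$n_genes + 1)
    truth <- vector("list", cfg$n_genes)
    offset <- 0L
    for (g in seq_len(cfg$n_genes)) {
      ig <- random_dna(stats::rpois(1, cfg$intergenic_len), cfg$gc_bias)
      pieces[2 * g - 1] <- ig
      offset <- offset + nchar(ig)
      d <- domain_of[g]
      rows <- which(db$acc == db$domains$acc[d])
      E <- db$emissions[rows, , drop = FALSE]
      aa_idx <- sample_aa_from_emissions(E)
      gene_aa <- aa[aa_idx]
      bad <- vapply(gene_aa, function(a) length(enc[[a]]$codons) == 0, TRUE)
      if (any(bad)) {
        stop("amino acid '", gene_aa[bad][1],
             "' has zero total codon weight under the code", call. = FALSE)
      }
      gene_codons <- vapply(gene_aa, function(a) {
        e <- enc[[a]]
        if (length(e$codons) == 1) e$codons else
          sample(e$codons, 1, prob = e$w)
      }, "")
      m <- length(gene_codons)
      strand <- if (g %% 2 == 1) "+" else "-"
      coding <- paste(gene_codons, collapse = "")
      if (strand == "+") {
        starts <- offset + 3L * (seq_len(m) - 1L)
        pieces[2 * g] <- coding
      } else {
        starts <- offset + 3L * (m - seq_len(m))
        pieces[2 * g] <- revcomp(coding)
      }
      truth[[g]] <- tibble::tibble(
        record_id = "synchrom", start = as.integer(starts), strand = strand,
        codon = gene_codons, acc = db$domains$acc[d],
        col_index = seq_len(m), aa = gene_aa)
      offset <- offset + 3L * m
    }
    pieces[2 * cfg$n_genes + 1] <-
      random_dna(stats::rpois(1, cfg$intergenic_len), cfg$gc_bias)
    seqs <- tibble::tibble(id = "synchrom",
                           seq = paste(pieces, collapse = ""),
                           source_offset = 0L)
    structure(list(seqs = seqs, truth = dplyr::bind_rows(truth),
                   config = cfg),
              class = "sim_genome")
  })
}

#' Emulate search output as aligned pairs
#'
#' Bypasses the external search program: emits the ground-truth
#' codon-column pairs with alignment posterior code `*` and E-value 1e-20,
#' plus a `noise` fraction of corrupted pairs whose consensus column is
#' replaced by a random column from the database, emulating
#' pseudogene/misalignment artifacts.
#'
#' @param truth Ground-truth pair tibble from [make_genome()] (`$truth`).
#' @param db The `profile_db` the genome was emitted from.
#' @param noise Fraction of pairs to corrupt, in \[0, 1).
#' @param seed RNG seed for the corruption draws.
#' @return An aligned-pair tibble compatible with [filter_pairs()] and
#'   [infer_genetic_code()].
#' @export
emulate_associations <- function(truth, db, noise = 0, seed = NULL) {
  stopifnot(noise >= 0, noise < 1)
  pairs <- tibble::tibble(
    codon = truth$codon, acc = truth$acc,
    name = db$domains$name[match(truth$acc, db$domains$acc)],
    col_index = truth$col_index,
    evalue = 1e-20, evalue_cond = 1e-20, pp = "*",
    record_id = truth$record_id, start = truth$start,
    strand = truth$strand)
  if (noise > 0 && nrow(pairs) > 0) {
    with_seed(if (is.null(seed)) NULL else sub_seed(seed, "noise"), {
      hit <- stats::runif(nrow(pairs)) < noise
      if (any(hit)) {
        repl <- sample.int(nrow(db$emissions), sum(hit), replace = TRUE)
        pairs$acc[hit] <- db$acc[repl]
        pairs$name[hit] <-
          db$domains$name[match(pairs$acc[hit], db$domains$acc)]
        pairs$col_index[hit] <- db$col_index[repl]
      }
    })
  }
  pairs
}

#' Run the whole emulated pipeline on a synthetic genome
#'
#' Convenience wrapper: generate profiles and a genome under `cfg`, emulate
#' the alignments, and decode all 64 codons. The ground truth is attached
#' for comparison.
#'
#' @param cfg A [sim_config()].
#' @param noise Corruption fraction for [emulate_associations()].
#' @param ... Passed to [infer_genetic_code()].
#' @return A `genetic_code_fit` with attributes `sim` (the `sim_genome`)
#'   and `db`.
#' @export
simulate_and_infer <- function(cfg, noise = 0.02, ...) {
  db <- make_profiles(cfg)
  sim <- make_genome(cfg, db)
  pairs <- emulate_associations(sim$truth, db, noise = noise,
                                seed = cfg$seed)
  fit <- infer_genetic_code(pairs, db, ...)
  attr(fit, "sim") <- sim
  attr(fit, "db") <- db
  fit
}

#' Synthetic per-codon consensus-column pools
#'
#' Builds, for every sense codon of `code`, a pool of consensus-column
#' emission vectors conserved for the codon's true amino acid: a
#' `1 - weak_frac` share of strong columns (Dirichlet, mean `strong_mean`
#' on the true amino acid) and a weak symmetric-Dirichlet admixture. These
#' pools drive the subsampling error/power benchmark.
#'
#' @param n_per_codon Columns per sense codon (default 2000).
#' @param code Ground-truth code; stop codons get no pool.
#' @param strong_mean,strong_conc,weak_frac,weak_conc As in [sim_config()].
#' @param seed RNG seed.
#' @return A named list of emission matrices (one per sense codon), class
#'   `codon_pools`, with attribute `truth` (named character vector of each
#'   codon's true amino acid).
#' @export
make_codon_pools <- function(n_per_codon = 2000L, code = standard_code(),
                             strong_mean = 0.6, strong_conc = 50,
                             weak_frac = 0.2, weak_conc = 1, seed = 2063L) {
  with_seed(sub_seed(seed, "pools"), {
    aa <- amino_acids()
    sense <- names(code)[code %in% aa]
    pools <- lapply(sense, function(z) {
      a <- match(code[[z]], aa)
      strong <- stats::runif(n_per_codon) >= weak_frac
      sim_emission_rows(rep(a, n_per_codon), strong, strong_mean,
                        strong_conc, weak_conc)
    })
    names(pools) <- sense
    structure(pools, class = "codon_pools",
              truth = stats::setNames(unname(code[sense]), sense))
  })
}

#' Per-codon pools from a genome's association sets
#'
#' Converts filtered, downsampled association sets into benchmark pools:
#' each codon's pool is its aligned columns' emission vectors, occurrences
#' expanded by count.
#'
#' @param assoc Association-set tibble.
#' @param db A `profile_db`.
#' @param truth Named character vector giving each codon's true amino acid
#'   (e.g. the ground-truth code restricted to sense codons).
#' @param min_pool Codons with fewer total occurrences are dropped.
#' @return A `codon_pools` object.
#' @export
pools_from_associations <- function(assoc, db, truth, min_pool = 1L) {
  keep <- assoc$n_total >= min_pool & assoc$codon %in% names(truth)
  pools <- lapply(which(keep), function(i) {
    x <- assoc$columns[[i]]
    rows <- db_rows(db, x$acc, x$col_index)
    db$emissions[rep(rows, x$count), , drop = FALSE]
  })
  names(pools) <- assoc$codon[keep]
  structure(pools, class = "codon_pools",
            truth = truth[names(pools)])
}

# occurrence-weighted background over all pool columns
pool_background <- function(pools) {
  clamp_renorm(colMeans(do.call(rbind, unclass(pools))))
}

#' Subsampling error/power benchmark
#'
#' For each codon and each subsample size, draws `n_reps` random subsamples
#' of consensus columns from the codon's pool, runs the 21-model decoding
#' posterior at `threshold`, and classifies each subsample as true (T,
#' correct amino acid inferred), false (F, incorrect amino acid inferred)
#' or uninferred (U, nonspecific model most probable or no model above
#' threshold). Per-codon error rate is F/(T+F+U) and power is T/(T+F+U).
#'
#' @param pools A `codon_pools` object.
#' @param sizes Integer vector of subsample sizes (default 1..50, 100, 500).
#' @param n_reps Subsamples per (codon, size); default 1000.
#' @param threshold Decoding probability threshold (default 0.9999).
#' @param bg Background frequencies; default: occurrence-weighted mean over
#'   all pools.
#' @param seed RNG seed.
#' @param replace Sample with replacement (default). Without replacement
#'   requires `size <= pool size`.
#' @return A tibble of class `error_power`: `codon`, `set_size`, `n_reps`,
#'   `n_true`, `n_false`, `n_uninferred`, `error_rate`, `power`.
#' @export
subsample_experiment <- function(pools, sizes = c(1:50, 100L, 500L),
                                 n_reps = 1000L, threshold = 0.9999,
                                 bg = NULL, seed = 2063L, replace = TRUE) {
  if (is.null(bg)) bg <- pool_background(pools)
  truth <- attr(pools, "truth")
  aa <- amino_acids()
  with_seed(sub_seed(seed, "subsampling"), {
    out <- vector("list", length(pools) * length(sizes))
    k_out <- 0L
    for (z in names(pools)) {
      E <- pools[[z]]
      Lr <- log(E) - rep(log(bg), each = nrow(E))
      true_idx <- match(truth[[z]], aa)
      grp_cache <- list()
      for (s in sizes) {
        k_out <- k_out + 1L
        if (s == 0) {
          out[[k_out]] <- tibble::tibble(
            codon = z, set_size = 0L, n_reps = n_reps, n_true = 0L,
            n_false = 0L, n_uninferred = n_reps, error_rate = 0,
            power = 0)
          next
        }
        idx <- if (replace) {
          sample.int(nrow(E), s * n_reps, replace = TRUE)
        } else {
          stopifnot(s <= nrow(E))
          as.vector(vapply(seq_len(n_reps),
                           function(i) sample.int(nrow(E), s), integer(s)))
        }
        key <- as.character(s)
        if (is.null(grp_cache[[key]])) {
          grp_cache[[key]] <- rep(seq_len(n_reps), each = s)
        }
        S <- rowsum(Lr[idx, , drop = FALSE], grp_cache[[key]])
        lp <- cbind(S, 0)
        m <- lp[cbind(seq_len(n_reps), max.col(lp, ties.method = "first"))]
        denom <- rowSums(exp(lp - m))
        win <- max.col(lp, ties.method = "first")
        post_win <- exp(0) / denom  # exp(lp_win - m) == 1
        assigned <- post_win > threshold & win <= 20L
        n_true <- sum(assigned & win == true_idx)
        n_false <- sum(assigned & win != true_idx)
        out[[k_out]] <- tibble::tibble(
          codon = z, set_size = as.integer(s), n_reps = as.integer(n_reps),
          n_true = n_true, n_false = n_false,
          n_uninferred = n_reps - n_true - n_false,
          error_rate = n_false / n_reps, power = n_true / n_reps)
      }
    }
    res <- dplyr::bind_rows(out)
    class(res) <- c("error_power", class(res))
    res
  })
}

#' Plot a subsampling error/power benchmark
#'
#' Power against subsample size, one line per codon, with the decoding
#' threshold regime this implies.
#'
#' @param object An `error_power` tibble from [subsample_experiment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.error_power <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = set_size, y = power, group = codon)) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 0.95, linetype = 2, color = "red") +
    ggplot2::scale_x_continuous(trans = "log10") +
    ggplot2::labs(x = "columns per subsample", y = "power (T / reps)") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.error_power
#' @param x An `error_power` tibble.
#' @exportS3Method generics::glance
glance.error_power <- function(x, ...) {
  at34 <- x[x$set_size == 34L, ]
  tibble::tibble(
    max_error = max(x$error_rate),
    min_power_34 = if (nrow(at34)) min(at34$power) else NA_real_,
    n_codons = length(unique(x$codon)),
    n_sizes = length(unique(x$set_size)),
    n_reps = max(x$n_reps))
}
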