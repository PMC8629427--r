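#' Background amino acid frequencies
#'
#' The background P(A) is the occurrence-weighted mean of the emission
#' vectors of every consensus column aligned to the target genome, pooled
#' over all 64 codons' (filtered, downsampled) association sets. Using the
#' aligned columns themselves, rather than the whole database, lets the
#' background reflect genome-specific amino acid biases. Entries are
#' clamped at 1e-6 and renormalized.
#'
#' @param assoc Association-set tibble (see [build_association_sets()]).
#' @param db A `profile_db`.
#' @return Named numeric vector of 20 probabilities in [amino_acids()]
#'   order.
#' @export
background_freqs <- function(assoc, db) {
  flat <- tidyr::unnest(assoc[, c("codon", "columns")], columns)
  if (nrow(flat) == 0 || sum(flat$count) == 0) {
    stop("no aligned columns; cannot infer", call. = FALSE)
  }
  E <- db$emissions[db_rows(db, flat$acc, flat$col_index), , drop = FALSE]
  p <- colSums(E * flat$count) / sum(flat$count)
  clamp_renorm(p)
}

#' Posterior over the 21 decoding models for one codon
#'
#' For a codon with aligned columns C1..CN (with occurrence counts), the
#' likelihood of decoding model M is the product over columns of
#' P(A=M|Ci)/P(A=M) for an amino acid model, and 1 for the nonspecific
#' model `?` (the factors P(Ci) common to all models and the uniform model
#' prior cancel in the posterior and are never represented). Computation is
#' in log space for numerical stability; the posterior is normalized over
#' all 21 models. An empty set yields the uniform posterior 1/21.
#'
#' @param columns A tibble `acc`, `col_index`, `count` (one codon's
#'   association set), or a row of the tibble from
#'   [build_association_sets()] via `assoc$columns[[i]]`.
#' @param db A `profile_db`.
#' @param bg Background frequencies from [background_freqs()].
#' @return A tibble of 21 rows: `model` (20 amino acid letters then `"?"`),
#'   `log_lik` (cancelled log-likelihood, 0 for `?`), `posterior`. The
#'   number of columns N is attached as attribute `n_columns`.
#' @export
decoding_posterior <- function(columns, db, bg) {
  aa <- amino_acids()
  if (is.null(columns) || nrow(columns) == 0) {
    ll <- rep(0, 21)
  } else {
    E <- db$emissions[db_rows(db, columns$acc, columns$col_index),
                      , drop = FALSE]
    ll <- c(unname(colSums(columns$count *
                             (log(E) - rep(log(bg), each = nrow(E))))), 0)
  }
  post <- exp(ll - max(ll))
  post <- post / sum(post)
  out <- tibble::tibble(model = c(aa, "?"), log_lik = ll, posterior = post)
  attr(out, "n_columns") <-
    if (is.null(columns)) 0L else as.integer(sum(columns$count))
  out
}

#' Assign a codon's translation from its decoding posterior
#'
#' Returns the amino acid whose posterior exceeds `threshold`, and `"?"`
#' otherwise -- including when the nonspecific model itself is the one with
#' high posterior. Because posteriors sum to 1, any threshold above 0.5
#' guarantees at most one model can exceed it.
#'
#' @param dp A posterior tibble from [decoding_posterior()], or a bare
#'   21-vector of posteriors in the same model order.
#' @param threshold Decoding probability threshold in (0.5, 1]; default
#'   0.9999.
#' @return A single character: an amino acid letter or `"?"`.
#' @export
assign_codon <- function(dp, threshold = 0.9999) {
  if (threshold <= 0.5 || threshold > 1) {
    stop("`threshold` must be in (0.5, 1]: a winner is only unique above 0.5",
         call. = FALSE)
  }
  post <- if (is.data.frame(dp)) dp$posterior else dp
  models <- if (is.data.frame(dp)) dp$model else c(amino_acids(), "?")
  i <- which.max(post)
  if (post[i] > threshold && models[i] != "?") models[i] else "?"
}

#' Infer the genetic code from filtered aligned pairs
#'
#' The data-frame-first core of the pipeline: takes aligned codon-column
#' pairs (from a real search via [pairs_from_hits()] or from the emulator
#' via [emulate_associations()]), applies the significance/certainty
#' filters, builds and downsamples the per-codon association sets, computes
#' the background and each codon's 21-model decoding posterior, and assigns
#' a translation per codon.
#'
#' @param pairs Aligned-pair tibble.
#' @param db A `profile_db`.
#' @param evalue_max,pp_min,excluded,evalue_col Filtering parameters, see
#'   [filter_pairs()].
#' @param cap_fraction Downsampling cap, see [downsample_associations()].
#' @param threshold Decoding probability threshold, see [assign_codon()].
#' @param background_mode Compute the background after (`"post_downsample"`,
#'   default) or before (`"pre_downsample"`) the 1 percent cap is applied.
#' @return A `genetic_code_fit` tibble with 64 rows in [codons()] order:
#'   `codon`, `n_columns` (post-filter, post-downsample N), `aa` (inferred
#'   letter or `"?"`), `posterior` (posterior of the inferred/top model),
#'   `posterior_unknown` (posterior of the nonspecific model). Attributes:
#'   `threshold`, `params`, `posteriors` (list of the 21-model posterior
#'   tibbles, for diagnostics), `background`.
#' @export
infer_genetic_code <- function(pairs, db, evalue_max = 1e-10, pp_min = 0.95,
                               excluded = character(), cap_fraction = 0.01,
                               threshold = 0.9999,
                               background_mode = c("post_downsample",
                                                   "pre_downsample"),
                               evalue_col = "evalue") {
  background_mode <- match.arg(background_mode)
  kept <- filter_pairs(pairs, evalue_max = evalue_max, pp_min = pp_min,
                       excluded = excluded, evalue_col = evalue_col)
  if (nrow(kept) == 0) {
    warning("no significant hits; inferring '?' for all 64 codons",
            call. = FALSE)
  }
  assoc <- build_association_sets(kept)
  down <- downsample_associations(assoc, cap_fraction = cap_fraction)
  bg_src <- if (background_mode == "post_downsample") down else assoc
  bg <- if (sum(bg_src$n_total) == 0) {
    clamp_renorm(rep(1 / 20, 20))
  } else {
    background_freqs(bg_src, db)
  }
  posts <- purrr::map(down$columns, decoding_posterior, db = db, bg = bg)
  aa <- vapply(posts, assign_codon, "", threshold = threshold)
  top <- vapply(posts, function(p) max(p$posterior), 0)
  unk <- vapply(posts, function(p) p$posterior[p$model == "?"], 0)
  out <- tibble::tibble(codon = down$codon, n_columns = down$n_total,
                        aa = aa, posterior = top, posterior_unknown = unk)
  structure(out,
            class = c("genetic_code_fit", class(out)),
            threshold = threshold,
            params = list(evalue_max = evalue_max, pp_min = pp_min,
                          cap_fraction = cap_fraction, threshold = threshold,
                          background_mode = background_mode,
                          evalue_col = evalue_col,
                          excluded = excluded),
            posteriors = posts, background = bg)
}

#' End-to-end genetic code inference from a genome FASTA
#'
#' Runs the full pipeline: read and chunk the genome, six-frame translate
#' under the standard code (stops as `'X'`), obtain profile alignments via
#' the chosen backend, convert to codon-column pairs, and decode all 64
#' codons with [infer_genetic_code()].
#'
#' @param genome Path to a genome FASTA (plain or gzipped).
#' @param db A `profile_db` object, or a path to a HMMER3 profile file.
#' @param backend `"hmmer"` to run `hmmscan`, or `"precomputed"` to parse
#'   an existing hmmscan output given in `search_output`. (The emulator
#'   backend bypasses the genome entirely: pass its pairs directly to
#'   [infer_genetic_code()].)
#' @param search_output Path to precomputed hmmscan text output (backend
#'   `"precomputed"`).
#' @param db_path Path of the profile database on disk; required for the
#'   hmmer backend when `db` is given as an object.
#' @param chunk_len Chunk length in nt (default 100000).
#' @param workdir Working directory for intermediate files.
#' @param ... Further arguments passed to [infer_genetic_code()]
#'   (thresholds, exclusions, ...).
#' @return A `genetic_code_fit` (see [infer_genetic_code()]) with an
#'   additional `run` attribute recording inputs and parameters.
#' @export
infer_code <- function(genome, db, backend = c("hmmer", "precomputed"),
                       search_output = NULL, db_path = NULL,
                       chunk_len = 100000L, workdir = tempdir(), ...) {
  backend <- match.arg(backend)
  if (is.character(db)) {
    db_path <- db
    db <- parse_profile_db(db)
  }
  seqs <- read_fasta(genome)
  chunks <- chunk_sequence(seqs, chunk_len = chunk_len)
  tr <- six_frame_translate(chunks)
  if (backend == "hmmer") {
    if (is.null(db_path)) {
      stop("hmmer backend needs `db_path` (a pressed HMMER3 file)",
           call. = FALSE)
    }
    pep <- file.path(workdir, "sixframe.faa")
    write_translations(tr, pep)
    search_output <- run_search(pep, db_path, workdir = workdir)
  } else if (is.null(search_output)) {
    stop("precomputed backend needs `search_output`", call. = FALSE)
  }
  hits <- parse_search_output(search_output)
  pairs <- pairs_from_hits(hits, tr, seqs, db = db)
  fit <- infer_genetic_code(pairs, db, ...)
  attr(fit, "run") <- list(genome = genome, backend = backend,
                           chunk_len = chunk_len,
                           search_output = search_output,
                           n_records = nrow(seqs), n_pairs = nrow(pairs))
  fit
}

#' @export
print.genetic_code_fit <- function(x, ...) {
  cat("<genetic_code_fit>  threshold", attr(x, "threshold"), "\n")
  cat("code:", code_string(x), "\n")
  NextMethod()
}

#' Tidy and summarize fitted genetic codes
#'
#' `tidy()` returns the per-codon table (the fit is already tidy; this
#' strips the class and adds the standard-code translation and a
#' `differs` flag). `glance()` returns one-row counts of assigned,
#' unassigned and nonstandard codons.
#'
#' @param x A `genetic_code_fit`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.genetic_code_fit <- function(x, ...) {
  std <- standard_code()
  tibble::as_tibble(x) |>
    dplyr::mutate(standard = unname(std[codon]),
                  differs = aa != "?" & aa != standard)
}

#' @rdname tidy.genetic_code_fit
#' @exportS3Method generics::glance
glance.genetic_code_fit <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    n_assigned = sum(td$aa != "?"),
    n_unassigned = sum(td$aa == "?"),
    n_nonstandard = sum(td$differs),
    median_n_columns = stats::median(td$n_columns),
    threshold = attr(x, "threshold"))
}

#' Plot a fitted genetic code
#'
#' A 16 x 4 codon table tiled by inferred translation, shaded by the
#' posterior of the inferred model, with nonstandard assignments outlined.
#'
#' @param object A `genetic_code_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.genetic_code_fit <- function(object, ...) {
  td <- tidy(object)
  td$first <- substr(td$codon, 1, 1)
  td$second <- substr(td$codon, 2, 2)
  td$third <- substr(td$codon, 3, 3)
  lv <- c("T", "C", "A", "G")
  td$row <- factor(paste0(td$first, td$third),
                   levels = rev(as.vector(outer(lv, lv, paste0))))
  td$second <- factor(td$second, levels = lv)
  ggplot2::ggplot(td, ggplot2::aes(x = second, y = row, fill = posterior)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::geom_tile(data = td[td$differs, ], fill = NA,
                       color = "red", linewidth = 0.8) +
    ggplot2::geom_text(ggplot2::aes(label = paste0(codon, "\n", aa)),
                       size = 2.6) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "second base", y = "first/third base",
                  fill = "posterior") +
    ggplot2::theme_minimal()
}

#' Write the per-codon inference TSV and JSON run report
#'
#' @param fit A `genetic_code_fit`.
#' @param tsv_path Per-codon TSV (codon, n_columns, inferred letter,
#'   posterior of inferred, posterior of `?`).
#' @param report_path JSON run report with all parameters.
#' @return `fit`, invisibly.
#' @export
write_code_report <- function(fit, tsv_path = NULL, report_path = NULL) {
  if (!is.null(tsv_path)) {
    readr::write_tsv(tibble::as_tibble(fit), tsv_path)
  }
  if (!is.null(report_path)) {
    rep <- list(code = code_string(fit),
                params = attr(fit, "params"),
                run = attr(fit, "run"),
                package_version = as.character(utils::packageVersion("codonscope")))
    jsonlite::write_json(rep, report_path, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
  }
  invisible(fit)
}
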