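#' Aggregate filtered pairs into per-codon association sets
#'
#' For each of the 64 codons, collects the multiset of profile consensus
#' columns aligned to instances of that codon across the whole input (the
#' per-codon C-to-Z set of size N). Every pair contributes exactly one
#' occurrence to exactly one codon's set; codons with no pairs get an empty
#' set.
#'
#' @param pairs A filtered aligned-pair tibble (columns `codon`, `acc`,
#'   `col_index`; see [filter_pairs()]).
#' @return A nested tibble with exactly 64 rows in [codons()] order:
#'   `codon`, `columns` (list-column of tibbles `acc`, `col_index`, `count`),
#'   `n_total` (sum of counts) and `n_original` (equal to `n_total` here;
#'   preserved unchanged by [downsample_associations()] so that the
#'   downsampling cap is always computed from the pre-downsampling total).
#' @export
build_association_sets <- function(pairs) {
  counted <- pairs |>
    dplyr::count(codon, acc, col_index, name = "count")
  empty <- tibble::tibble(acc = character(), col_index = integer(),
                          count = integer())
  cols <- purrr::map(codons(), function(z) {
    sub <- counted[counted$codon == z, c("acc", "col_index", "count")]
    if (nrow(sub) == 0) empty else sub
  })
  n_tot <- vapply(cols, function(x) sum(x$count), 0)
  tibble::tibble(codon = codons(), columns = cols,
                 n_total = as.integer(n_tot),
                 n_original = as.integer(n_tot))
}

# cap for one codon given its pre-downsampling total
downsample_cap <- function(n_original, cap_fraction) {
  if (n_original >= 100) max(1L, as.integer(floor(cap_fraction * n_original)))
  else 1L
}

#' Downsample over-represented consensus columns
#'
#' Mitigates artifacts such as repetitive pseudogene families by capping
#' how much any single consensus column may contribute to a codon's set:
#' if the codon has at least 100 aligned columns in total, no column may
#' account for more than `cap_fraction` (default 1%) of the
#' pre-downsampling total; below 100, every unique column is reduced to a
#' single occurrence. A computed cap of zero is raised to one so that a
#' column that legitimately aligned always retains one vote.
#'
#' Occurrences of a column are exchangeable once aggregated to counts, so
#' removal reduces to `count = min(count, cap)` and is deterministic;
#' `rng_seed` is accepted for interface stability but has no effect.
#' The cap is always computed from `n_original`, making the operation
#' idempotent.
#'
#' @param assoc An association-set tibble from [build_association_sets()].
#' @param cap_fraction Maximum fraction of a codon's total that one column
#'   may contribute (default 0.01); must be in (0, 1].
#' @param rng_seed Unused (see above).
#' @return The association-set tibble with capped counts and updated
#'   `n_total`; `n_original` is preserved.
#' @export
downsample_associations <- function(assoc, cap_fraction = 0.01,
                                    rng_seed = NULL) {
  stopifnot(cap_fraction > 0, cap_fraction <= 1)
  cols <- purrr::map2(assoc$columns, assoc$n_original, function(x, n0) {
    if (nrow(x) == 0) return(x)
    cap <- downsample_cap(n0, cap_fraction)
    x$count <- pmin(x$count, cap)
    x
  })
  assoc$columns <- cols
  assoc$n_total <- vapply(cols, function(x) as.integer(sum(x$count)), 0L)
  assoc
}

#' Serialize/deserialize association sets as TSV
#'
#' A flat TSV (codon, acc, col_index, count) for inspection and for
#' replaying inference without re-running the search.
#'
#' @param assoc Association-set tibble.
#' @param path File path.
#' @return `path` invisibly, or the association-set tibble.
#' @export
write_association_sets <- function(assoc, path) {
  flat <- tidyr::unnest(assoc[, c("codon", "columns")], columns)
  readr::write_tsv(flat, path)
  invisible(path)
}

#' @rdname write_association_sets
#' @export
read_association_sets <- function(path) {
  flat <- readr::read_tsv(path, show_col_types = FALSE,
                          col_types = readr::cols(
                            codon = "c", acc = "c",
                            col_index = "i", count = "i"))
  build_association_sets(flat[rep(seq_len(nrow(flat)), flat$count),
                              c("codon", "acc", "col_index")])
}
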