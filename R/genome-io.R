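#' Read nucleotide sequences from FASTA
#'
#' Reads plain or gzip-compressed FASTA. Sequences are upper-cased and RNA
#' input is accepted (U is mapped to T). Any character outside the IUPAC
#' nucleotide alphabet is an error naming the record and position.
#'
#' @param path Path to a FASTA or gzipped FASTA file.
#' @return A tibble with one row per record: `id` (first whitespace-delimited
#'   token of the header), `seq` (upper-case DNA string) and `source_offset`
#'   (0-based position of this sequence within its parent record; 0 for
#'   freshly read records, set by [chunk_sequence()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- chartr("U", "T", toupper(as.character(set)))
  iupac <- "ACGTUMRWSYKVHDBN"
  for (i in seq_along(seqs)) {
    bad <- regexpr(sprintf("[^%s]", iupac), seqs[[i]])
    if (bad != -1L) {
      stop(sprintf("non-IUPAC character '%s' in record '%s' at position %d",
                   substr(seqs[[i]], bad, bad), ids[[i]], bad), call. = FALSE)
    }
    if (nchar(seqs[[i]]) == 0) {
      stop("empty sequence in record '", ids[[i]], "'", call. = FALSE)
    }
  }
  tibble::tibble(id = ids, seq = unname(seqs), source_offset = 0L)
}

#' Split sequences into non-overlapping chunks
#'
#' Long sequences are broken into non-overlapping pieces (100 kb by default)
#' before translation; codons overlapping a chunk boundary are lost, an
#' accepted edge effect of at most two codons per boundary per frame.
#'
#' @param seqs A tibble as returned by [read_fasta()] (columns `id`, `seq`,
#'   `source_offset`).
#' @param chunk_len Chunk length in nucleotides (default 100000, minimum 3).
#' @return A tibble with the same columns plus `chunk` (1-based chunk index
#'   within the parent record); `source_offset` gives each chunk's 0-based
#'   start in the parent. Concatenating a record's chunk sequences
#'   reproduces the input.
#' @export
chunk_sequence <- function(seqs, chunk_len = 100000L) {
  stopifnot(chunk_len >= 3)
  purrr::pmap_dfr(seqs, function(id, seq, source_offset, ...) {
    n <- nchar(seq)
    starts <- seq.int(0L, n - 1L, by = chunk_len)
    tibble::tibble(
      id = id,
      seq = substring(seq, starts + 1L, pmin(starts + chunk_len, n)),
      source_offset = as.integer(source_offset + starts),
      chunk = seq_along(starts)
    )
  })
}

# reverse complement preserving IUPAC ambiguity codes
revcomp <- function(x) {
  comp <- chartr("ACGTMRWSYKVHDBN", "TGCAKYWSRMBDHVN", x)
  vapply(strsplit(comp, ""), function(ch) paste(rev(ch), collapse = ""), "")
}

# codons of `seq` starting at 0-based offsets `starts` (forward strand)
codons_at <- function(seq, starts) {
  substring(seq, starts + 1L, starts + 3L)
}

#' Six-frame translation with coordinate maps
#'
#' Translates each input sequence in all six reading frames under the
#' standard genetic code, with stop codons and any codon containing a
#' non-ACGT base rendered as `'X'` (treated downstream as an unknown
#' residue). Every peptide position carries the 0-based forward-strand
#' coordinate of its codon so alignments can be mapped back to genomic
#' codons exactly.
#'
#' Frames 0-2 are the forward strand with offsets 0, 1, 2; frames 3-5 are
#' the reverse complement with offsets 0, 1, 2. For reverse frames,
#' `codon_starts` give the forward-strand coordinate of the codon's
#' 5'-most forward-strand base (i.e. the smallest coordinate of the 3-nt
#' span).
#'
#' @param seqs A tibble of sequences (`id`, `seq`, `source_offset`, and
#'   optionally `chunk`).
#' @return A tibble with one row per (record, frame): `parent_id`, `chunk`,
#'   `source_offset`, `frame` (0-5), `strand` (`"+"`/`"-"`), `peptide`, and
#'   `codon_starts` (list-column of integer vectors, one start per peptide
#'   position, in chunk-local coordinates).
#' @export
six_frame_translate <- function(seqs) {
  if (!"chunk" %in% names(seqs)) seqs$chunk <- 1L
  code <- standard_code()
  purrr::pmap_dfr(seqs, function(id, seq, source_offset, chunk, ...) {
    n <- nchar(seq)
    rc <- revcomp(seq)
    purrr::map_dfr(0:5, function(f) {
      off <- f %% 3L
      n_cod <- max((n - off) %/% 3L, 0L)
      if (n_cod == 0L) {
        starts <- integer(0)
        pep <- ""
      } else if (f < 3L) {
        starts <- off + 3L * (seq_len(n_cod) - 1L)
        pep <- paste(translate_codons(codons_at(seq, starts), code),
                     collapse = "")
      } else {
        rc_starts <- off + 3L * (seq_len(n_cod) - 1L)
        pep <- paste(translate_codons(codons_at(rc, rc_starts), code),
                     collapse = "")
        starts <- n - 3L - rc_starts
      }
      tibble::tibble(parent_id = id, chunk = chunk,
                     source_offset = as.integer(source_offset),
                     frame = f, strand = if (f < 3L) "+" else "-",
                     peptide = pep, codon_starts = list(as.integer(starts)))
    })
  })
}

#' Translation-stage FASTA headers
#'
#' The six-frame peptides are written with headers of the form
#' `<parent>|chunk<k>|frame<f>` so that search hits can be mapped back to
#' their source chunk and frame.
#'
#' @param tr A six-frame translation tibble.
#' @return Character vector of query ids, one per row of `tr`.
#' @export
translation_query_id <- function(tr) {
  sprintf("%s|chunk%d|frame%d", tr$parent_id, tr$chunk, tr$frame)
}

#' Write six-frame peptides as FASTA (plus a coordinate-map TSV)
#'
#' @param tr A tibble from [six_frame_translate()].
#' @param fasta_path Output FASTA path for the peptides.
#' @param map_path Optional path for a sidecar TSV coordinate map (one row
#'   per peptide position: query id, position, chunk-local codon start,
#'   strand, chunk offset).
#' @return `fasta_path`, invisibly.
#' @export
write_translations <- function(tr, fasta_path, map_path = NULL) {
  qid <- translation_query_id(tr)
  keep <- nchar(tr$peptide) > 0
  lines <- as.vector(rbind(paste0(">", qid[keep]), tr$peptide[keep]))
  writeLines(lines, fasta_path)
  if (!is.null(map_path)) {
    map <- tidyr::unnest(
      dplyr::mutate(tr, query = qid,
                    pos = purrr::map(codon_starts, seq_along)),
      c(pos, codon_starts))
    readr::write_tsv(
      dplyr::select(map, query, pos, codon_start = codon_starts, strand,
                    source_offset),
      map_path)
  }
  invisible(fasta_path)
}

#' Write a sequence tibble as FASTA
#'
#' @param seqs A tibble with `id` and `seq` columns.
#' @param path Output path; a `.gz` suffix writes gzip-compressed output.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(as.vector(rbind(paste0(">", seqs$id), seqs$seq)), con)
  invisible(path)
}

#' Translate open reading frames under an arbitrary genetic code
#'
#' Finds all six-frame open reading frames (maximal codon stretches between
#' stop codons, where the stop set is the codons the table maps to `"*"`)
#' longer than `min_len` codons and translates them with `code`. Codons
#' mapped to `"?"` (candidate reassigned codons) and codons containing
#' non-ACGT bases are emitted as `'X'`.
#'
#' @param seqs A sequence tibble (`id`, `seq`).
#' @param code A 64-entry genetic code vector (see [standard_code()]);
#'   may contain `"?"` entries.
#' @param min_len Minimum ORF length in codons; ORFs must be strictly
#'   longer than this (default 50).
#' @return A tibble: `id`, `frame`, `start` (chunk-local, 0-based, of the
#'   first codon), `peptide`.
#' @export
orf_translate <- function(seqs, code = standard_code(), min_len = 50L) {
  if (length(code) != 64 || is.null(names(code))) {
    stop("`code` must be a complete named 64-codon table", call. = FALSE)
  }
  empty <- tibble::tibble(id = character(), frame = integer(),
                          start = integer(), peptide = character())
  tr <- six_frame_translate(seqs)
  res <- purrr::pmap_dfr(tr, function(parent_id, frame, peptide, codon_starts,
                               strand, ...) {
    starts <- codon_starts
    n <- length(starts)
    if (n == 0) return(empty)
    # re-derive codons in the translated orientation
    cdn <- character(n)
    seq <- seqs$seq[match(parent_id, seqs$id)]
    fwd <- codons_at(seq, starts)
    cdn <- if (strand == "+") fwd else revcomp(fwd)
    aa <- translate_codons(cdn, code, stop_char = "*", unknown_char = "X")
    is_stop <- aa == "*"
    grp <- cumsum(is_stop)
    out <- list()
    for (g in split(seq_len(n)[!is_stop], grp[!is_stop])) {
      if (length(g) > min_len) {
        out[[length(out) + 1]] <- tibble::tibble(
          id = parent_id, frame = frame, start = starts[g[1]],
          peptide = paste(aa[g], collapse = ""))
      }
    }
    dplyr::bind_rows(out)
  })
  if (nrow(res) == 0) empty else res
}
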