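#' Run a profile search of six-frame peptides against a profile database
#'
#' Invokes `hmmscan` on the translated peptides, producing its full text
#' output (including per-residue alignment posterior annotation), which
#' [parse_search_output()] consumes. The database is pressed with
#' `hmmpress` on first use.
#'
#' @param peptides Path to a peptide FASTA (see [write_translations()]).
#' @param db Path to a HMMER3 profile database file.
#' @param workdir Directory for the raw output (created if needed).
#' @param hmmscan Name/path of the hmmscan executable.
#' @return Path to the raw search output.
#' @export
run_search <- function(peptides, db, workdir = tempdir(),
                       hmmscan = "hmmscan") {
  if (!dir.exists(workdir)) dir.create(workdir, recursive = TRUE)
  out <- file.path(workdir, "search_output.txt")
  if (!any(startsWith(readLines(peptides, warn = FALSE), ">"))) {
    writeLines("# no query sequences", out)  # empty query set: empty hit set
    return(out)
  }
  if (Sys.which(hmmscan) == "") {
    stop("hmmscan executable not found on PATH; install HMMER or use the ",
         "emulator backend (see emulate_associations())", call. = FALSE)
  }
  if (!file.exists(paste0(db, ".h3m"))) {
    st <- system2("hmmpress", c("-f", shQuote(db)), stdout = FALSE,
                  stderr = FALSE)
    if (st != 0) stop("hmmpress failed on ", db, call. = FALSE)
  }
  res <- suppressWarnings(system2(hmmscan,
    c("--notextw", "-o", shQuote(out), shQuote(db), shQuote(peptides)),
    stdout = TRUE, stderr = TRUE))
  st <- attr(res, "status")
  if (!is.null(st) && st != 0) {
    stop("hmmscan failed (exit ", st, "): ",
         paste(utils::tail(res, 5), collapse = "\n"), call. = FALSE)
  }
  out
}

# map a per-residue posterior code to the lower bound of its probability
# bin: digit d covers ((d-0.5)/10, (d+0.5)/10]; '*' covers (0.95, 1]
pp_lower_bound <- function(pp) {
  ifelse(pp == "*", 0.95, (match(pp, as.character(0:9)) - 1 - 0.5) / 10)
}

#' Parse hmmscan alignment-bearing text output
#'
#' Recovers, for every reported domain hit, the per-position correspondence
#' between query peptide positions and profile consensus columns, skipping
#' insert states and query deletions, together with the per-position
#' alignment posterior code and the domain's conditional and independent
#' E-values.
#'
#' @param path Path to hmmscan text output (as written by [run_search()]).
#' @return A tibble with one row per aligned (peptide position, consensus
#'   column) pair: `query`, `target` (profile name), `domain_idx`,
#'   `evalue` (independent/per-domain), `evalue_cond` (conditional),
#'   `qpos` (1-based peptide position), `col_index` (consensus column),
#'   `pp` (posterior code character).
#' @export
parse_search_output <- function(path) {
  lines <- readLines(path)
  empty <- tibble::tibble(
    query = character(), target = character(), domain_idx = integer(),
    evalue = numeric(), evalue_cond = numeric(), qpos = integer(),
    col_index = integer(), pp = character())
  out <- list()
  query <- NA_character_
  target <- NA_character_
  dom_tab <- NULL  # per-target table of domain E-values
  i <- 1L
  n <- length(lines)
  # state for an open alignment block
  aln <- NULL
  flush_aln <- function(aln) {
    if (is.null(aln) || !nzchar(aln$model)) return(NULL)
    mod <- strsplit(aln$model, "")[[1]]
    qry <- strsplit(aln$query, "")[[1]]
    pp <- strsplit(aln$pp, "")[[1]]
    if (length(mod) != length(qry) || length(mod) != length(pp)) {
      stop("truncated alignment block for query '", aln$qname,
           "' vs '", aln$tname, "'", call. = FALSE)
    }
    hmm_pos <- aln$hmmfrom - 1L
    q_pos <- aln$alifrom - 1L
    rows <- vector("list", length(mod))
    k <- 0L
    for (j in seq_along(mod)) {
      is_match <- mod[j] != "."
      has_res <- qry[j] != "-"
      if (is_match) hmm_pos <- hmm_pos + 1L
      if (has_res) q_pos <- q_pos + 1L
      if (is_match && has_res) {
        k <- k + 1L
        rows[[k]] <- c(q_pos, hmm_pos, j)
      }
    }
    if (k == 0L) return(NULL)
    m <- do.call(rbind, rows[seq_len(k)])
    tibble::tibble(query = aln$qname, target = aln$tname,
                   domain_idx = aln$dom,
                   evalue = aln$ieval, evalue_cond = aln$ceval,
                   qpos = as.integer(m[, 1]), col_index = as.integer(m[, 2]),
                   pp = pp[m[, 3]])
  }
  while (i <= n) {
    ln <- lines[i]
    if (startsWith(ln, "Query:")) {
      query <- strsplit(trimws(substring(ln, 7)), "\\s+")[[1]][1]
    } else if (startsWith(ln, ">> ")) {
      target <- strsplit(trimws(substring(ln, 4)), "\\s+")[[1]][1]
      dom_tab <- list()
    } else if (grepl("^\\s+\\d+\\s+[!?]\\s", ln) && !is.null(dom_tab)) {
      tk <- strsplit(trimws(ln), "\\s+")[[1]]
      # # ! score bias c-Evalue i-Evalue hmmfrom hmmto .. alifrom alito ...
      dom_tab[[tk[1]]] <- list(ceval = as.numeric(tk[5]),
                               ieval = as.numeric(tk[6]))
    } else if (grepl("^\\s+== domain", ln)) {
      tk <- strsplit(trimws(ln), "\\s+")[[1]]
      dom <- as.integer(tk[3])
      ev <- dom_tab[[as.character(dom)]]
      if (is.null(ev)) {
        stop("alignment for unreported domain ", dom, " of '", target,
             "' (truncated stream?)", call. = FALSE)
      }
      # consume wrapped alignment segments until blank line followed by
      # something that is not an annotation/model line
      aln <- list(qname = query, tname = target, dom = dom,
                  ceval = ev$ceval, ieval = ev$ieval,
                  hmmfrom = NA_integer_, alifrom = NA_integer_,
                  model = "", query = "", pp = "")
      i <- i + 1L
      seg <- character()
      while (i <= n) {
        ln2 <- lines[i]
        if (grepl(" PP\\s*$", ln2)) {
          seg_pp <- ln2
          # walk back: query line, match line, model line
          qline <- lines[i - 1L]
          mline <- lines[i - 3L]
          mt <- strsplit(trimws(mline), "\\s+")[[1]]
          qt <- strsplit(trimws(qline), "\\s+")[[1]]
          if (length(mt) < 4 || length(qt) < 4) {
            stop("unparseable alignment segment for '", target,
                 "' near line ", i, call. = FALSE)
          }
          if (is.na(aln$hmmfrom)) aln$hmmfrom <- as.integer(mt[2])
          if (is.na(aln$alifrom)) aln$alifrom <- as.integer(qt[2])
          aln$model <- paste0(aln$model, mt[3])
          aln$query <- paste0(aln$query, qt[3])
          # pp string is the single token before the trailing 'PP'
          pt <- strsplit(trimws(seg_pp), "\\s+")[[1]]
          aln$pp <- paste0(aln$pp, pt[length(pt) - 1L])
          i <- i + 1L
        } else if (grepl("^\\s*$", ln2)) {
          nxt <- if (i + 1L <= n) lines[i + 1L] else ""
          if (grepl("^\\s+\\S+\\s+\\d+\\s+\\S+\\s+\\d+", nxt) &&
              !grepl("^\\s+== domain", nxt) && !startsWith(nxt, ">> ")) {
            i <- i + 1L  # wrapped continuation follows
          } else break
        } else {
          i <- i + 1L
        }
      }
      out[[length(out) + 1]] <- flush_aln(aln)
      aln <- NULL
    }
    i <- i + 1L
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}

#' Convert parsed search hits to codon-column aligned pairs
#'
#' Maps each aligned peptide position back to its genomic codon using the
#' six-frame coordinate maps, and extracts the codon sequence from the
#' parent record. Pairs whose codon contains a non-ACGT base are dropped:
#' the decoding model needs an unambiguous 64-way codon identity. Codons
#' that were translated as `'X'` because they are stop codons are retained;
#' these in-frame stop alignments are exactly the signal used to detect
#' stop-codon reassignment.
#'
#' @param hits Tibble from [parse_search_output()].
#' @param translations Tibble from [six_frame_translate()].
#' @param seqs The original (unchunked) sequence tibble from [read_fasta()].
#' @param db Optional `profile_db` used to resolve profile names to
#'   accessions; without it `acc` is the profile name.
#' @return An aligned-pair tibble: `codon`, `acc`, `name`, `col_index`,
#'   `evalue`, `evalue_cond`, `pp`, `record_id`, `start` (0-based
#'   forward-strand genomic coordinate in the parent record), `strand`.
#' @export
pairs_from_hits <- function(hits, translations, seqs, db = NULL) {
  if (nrow(hits) == 0) {
    return(tibble::tibble(
      codon = character(), acc = character(), name = character(),
      col_index = integer(), evalue = numeric(), evalue_cond = numeric(),
      pp = character(), record_id = character(), start = integer(),
      strand = character()))
  }
  qids <- translation_query_id(translations)
  row <- match(hits$query, qids)
  if (anyNA(row)) {
    stop("unknown query id: ", hits$query[is.na(row)][1], call. = FALSE)
  }
  starts_local <- purrr::map2_int(row, hits$qpos, function(r, p) {
    cs <- translations$codon_starts[[r]]
    if (p < 1 || p > length(cs)) {
      stop("peptide position ", p, " outside coordinate map", call. = FALSE)
    }
    cs[p]
  })
  record_id <- translations$parent_id[row]
  strand <- translations$strand[row]
  start <- translations$source_offset[row] + starts_local
  parent <- match(record_id, seqs$id)
  fwd <- codons_at(seqs$seq[parent], start)
  codon <- ifelse(strand == "+", fwd, revcomp(fwd))
  name <- hits$target
  acc <- if (!is.null(db)) {
    a <- db$domains$acc[match(name, db$domains$name)]
    ifelse(is.na(a), name, a)
  } else name
  keep <- !grepl("[^ACGT]", codon)
  tibble::tibble(codon = codon, acc = acc, name = name,
                 col_index = hits$col_index, evalue = hits$evalue,
                 evalue_cond = hits$evalue_cond, pp = hits$pp,
                 record_id = record_id, start = start,
                 strand = strand)[keep, ]
}

#' Filter aligned pairs by significance, alignment certainty and exclusions
#'
#' Keeps pairs whose per-domain independent E-value is strictly below
#' `evalue_max` (default 1e-10), whose per-residue alignment posterior code
#' bin lies entirely at or above `pp_min` (default 0.95, so only the `*`
#' code, denoting posterior > 0.95, passes), and whose profile is not
#' matched by the exclusion patterns. A pure filter: output is a subset of
#' input, order preserved, idempotent.
#'
#' @param pairs An aligned-pair tibble (see [pairs_from_hits()]).
#' @param evalue_max E-value threshold (strict inequality).
#' @param pp_min Minimum alignment posterior, as a fraction.
#' @param excluded Character vector of accession/name glob patterns (see
#'   [load_exclusion_list()]).
#' @param evalue_col Which E-value to threshold: `"evalue"` (per-domain
#'   independent, the default) or `"evalue_cond"` (conditional).
#' @return The filtered pair tibble.
#' @export
filter_pairs <- function(pairs, evalue_max = 1e-10, pp_min = 0.95,
                         excluded = character(), evalue_col = "evalue") {
  keep <- pairs[[evalue_col]] < evalue_max &
    pp_lower_bound(pairs$pp) >= pp_min
  if (length(excluded) > 0) {
    ex <- matches_exclusion(pairs$acc, excluded)
    if ("name" %in% names(pairs)) {
      ex <- ex | matches_exclusion(pairs$name, excluded)
    }
    keep <- keep & !ex
  }
  pairs[keep & !is.na(keep), ]
}
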