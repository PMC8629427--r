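#' @title Profile databases of consensus-column emission vectors
#' @description A `profile_db` holds, for every consensus (match) column of
#'   every protein-domain profile, a 20-way amino acid emission probability
#'   vector in [amino_acids()] order. Only match-state emissions are used;
#'   insert states and transition parameters are ignored. Emissions are
#'   clamped at a floor of 1e-6 and renormalized so that no downstream log
#'   is ever taken of zero.
#' @name profile_db
NULL

EMISSION_FLOOR <- 1e-6

clamp_renorm <- function(p, floor = EMISSION_FLOOR) {
  p <- pmax(p, floor)
  p / sum(p)
}

new_profile_db <- function(domains, emissions, acc, col_index) {
  stopifnot(nrow(emissions) == length(acc), length(acc) == length(col_index))
  colnames(emissions) <- amino_acids()
  structure(
    list(domains = domains, emissions = emissions,
         acc = acc, col_index = as.integer(col_index),
         rowkey = paste0(acc, "#", col_index)),
    class = "profile_db")
}

#' @export
print.profile_db <- function(x, ...) {
  cat(sprintf("<profile_db> %d domains, %d consensus columns\n",
              nrow(x$domains), nrow(x$emissions)))
  print(x$domains, n = 5)
  invisible(x)
}

#' @describeIn profile_db One row per consensus column: `acc`, `name`,
#'   `col_index`, and the 20 emission probabilities.
#' @param x A `profile_db`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.profile_db <- function(x, ...) {
  dplyr::left_join(
    tibble::tibble(acc = x$acc, col_index = x$col_index),
    x$domains[, c("acc", "name")], by = "acc") |>
    dplyr::relocate(acc, name, col_index) |>
    dplyr::bind_cols(tibble::as_tibble(x$emissions))
}

# row indices into db$emissions for (acc, col_index) pairs; error on misses
db_rows <- function(db, acc, col_index) {
  i <- match(paste0(acc, "#", col_index), db$rowkey)
  if (anyNA(i)) {
    miss <- paste0(acc, "#", col_index)[is.na(i)][1]
    stop("unknown consensus column: ", miss, call. = FALSE)
  }
  i
}

#' Parse a HMMER3 ASCII profile database
#'
#' Reads one or many concatenated profiles in HMMER3 ASCII format and
#' extracts per-consensus-column match emission vectors. Stored values are
#' negative natural-log probabilities; they are converted with
#' `p = exp(-v)`, `*` entries (impossible emissions) become probability 0,
#' and each column is clamped at 1e-6 and renormalized to sum to 1.
#'
#' @param path Path to a HMMER3 ASCII profile file (e.g. output of
#'   `hmmbuild`, possibly a concatenation of many profiles).
#' @return A `profile_db` object.
#' @export
parse_profile_db <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  aa_n <- 20L
  domains <- list()
  emis <- list()
  accs <- list()
  cols <- list()
  i <- 1L
  n <- length(lines)
  bad <- function(i, name, msg) {
    stop(sprintf("malformed profile '%s' at line %d: %s", name, i, msg),
         call. = FALSE)
  }
  while (i <= n) {
    if (!startsWith(lines[i], "HMMER3")) {
      if (grepl("^\\s*$", lines[i])) { i <- i + 1L; next }
      bad(i, "?", "expected HMMER3 header")
    }
    name <- NA_character_; acc <- NA_character_; leng <- NA_integer_
    i <- i + 1L
    # header block until the 'HMM' column-label line
    while (i <= n && !grepl("^HMM\\s", lines[i])) {
      key <- substr(lines[i], 1, 5)
      val <- trimws(substring(lines[i], 6))
      if (startsWith(key, "NAME")) name <- val
      if (startsWith(key, "ACC")) acc <- val
      if (startsWith(key, "LENG")) leng <- as.integer(val)
      i <- i + 1L
    }
    if (i > n) bad(i - 1L, name, "truncated header (no HMM line)")
    if (is.na(name) || is.na(leng)) bad(i, name, "missing NAME or LENG")
    if (is.na(acc)) acc <- name
    i <- i + 2L  # skip 'HMM ...' label line and transition label line
    toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(toks) > 0 && toks[1] == "COMPO") i <- i + 1L
    i <- i + 2L  # node-0 insert emissions and transitions
    E <- matrix(0, nrow = leng, ncol = aa_n)
    for (k in seq_len(leng)) {
      if (i > n) bad(i - 1L, name, "truncated match states")
      toks <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      if (length(toks) < 1 + aa_n || suppressWarnings(is.na(as.integer(toks[1]))) ||
          as.integer(toks[1]) != k) {
        bad(i, name, sprintf("expected match state %d", k))
      }
      v <- toks[2:(1 + aa_n)]
      p <- ifelse(v == "*", 0, exp(-suppressWarnings(as.numeric(v))))
      if (anyNA(p)) bad(i, name, "non-numeric emission")
      E[k, ] <- clamp_renorm(p)
      i <- i + 3L  # skip insert emission and transition lines
    }
    while (i <= n && !startsWith(lines[i], "//")) i <- i + 1L
    if (i > n) bad(n, name, "missing '//' terminator")
    i <- i + 1L
    if (acc %in% vapply(domains, function(d) d$acc, "")) {
      stop("duplicate accession: ", acc, call. = FALSE)
    }
    domains[[length(domains) + 1]] <-
      tibble::tibble(acc = acc, name = name, length = leng)
    emis[[length(emis) + 1]] <- E
    accs[[length(accs) + 1]] <- rep(acc, leng)
    cols[[length(cols) + 1]] <- seq_len(leng)
  }
  if (length(domains) == 0) stop("no profiles found in ", path, call. = FALSE)
  new_profile_db(dplyr::bind_rows(domains), do.call(rbind, emis),
                 unlist(accs), unlist(cols))
}

#' Serialize a profile database to HMMER3 ASCII
#'
#' Writes each domain as a minimal HMMER3/f profile with match-state
#' emissions stored as negative natural-log probabilities at full double
#' precision, so that [parse_profile_db()] round-trips emissions within
#' 1e-9. Insert emissions and transitions are filled with flat defaults;
#' they carry no information used by this package.
#'
#' @param db A `profile_db`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_profile_db <- function(db, path) {
  aa <- amino_acids()
  con <- file(path, "w")
  on.exit(close(con))
  tr_hdr <- paste0(" ", paste(sprintf("%8s",
    c("m->m", "m->i", "m->d", "i->m", "i->i", "d->m", "d->d")), collapse = " "))
  flat <- paste(sprintf("%8.5f", rep(2.99573, 20)), collapse = " ")
  trans <- paste(sprintf("%8s",
    c("0.01", "4.62", "4.62", "0.62", "0.77", "0.00", "*")), collapse = " ")
  for (d in seq_len(nrow(db$domains))) {
    acc <- db$domains$acc[d]
    rows <- which(db$acc == acc)
    L <- db$domains$length[d]
    writeLines(c(
      "HMMER3/f [3.1b2 | February 2015]",
      paste0("NAME  ", db$domains$name[d]),
      paste0("ACC   ", acc),
      paste0("LENG  ", L),
      "ALPH  amino",
      "RF    no",
      "MM    no",
      "CONS  yes",
      "CS    no",
      "MAP   yes",
      "NSEQ  100",
      "EFFN  100.0",
      "STATS LOCAL MSV       -9.0000  0.70000",
      "STATS LOCAL VITERBI  -10.0000  0.70000",
      "STATS LOCAL FORWARD   -4.0000  0.70000",
      paste0("HMM     ", paste(sprintf("%8s", aa), collapse = " ")),
      tr_hdr,
      paste0("  COMPO   ", flat),
      paste0("          ", flat),
      paste0("          ", trans)), con)
    for (k in seq_len(L)) {
      p <- db$emissions[rows[k], ]
      v <- sprintf("%.12g", -log(p))
      cons <- aa[which.max(p)]
      writeLines(c(
        sprintf("%7d   %s %6d %s - - -", k,
                paste(sprintf("%12s", v), collapse = " "), k, cons),
        paste0("          ", flat),
        paste0("          ", trans)), con)
    }
    writeLines("//", con)
  }
  invisible(path)
}

#' Load a profile exclusion list
#'
#' The screen excludes hits to classes of profiles whose emission structure
#' misleads codon decoding (mitochondrial, viral, selenoprotein- and
#' pyrrolysine-containing, and mobile-element proteins). The list ships as a
#' user-editable file of accessions or name globs, one per line; `#` starts
#' a comment.
#'
#' @param path Path to the exclusion file.
#' @return Character vector of accession/name glob patterns (possibly
#'   empty).
#' @export
load_exclusion_list <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

# TRUE for each x matching any glob pattern (exact match when no wildcard)
matches_exclusion <- function(x, patterns) {
  if (length(patterns) == 0) return(rep(FALSE, length(x)))
  hit <- rep(FALSE, length(x))
  for (p in patterns) {
    hit <- hit | grepl(utils::glob2rx(p), x)
  }
  hit
}
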