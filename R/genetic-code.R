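#' Canonical amino acid order
#'
#' All 20-valued emission and background vectors in this package are indexed
#' by amino acid one-letter code in this fixed order.
#'
#' @return Character vector of the 20 amino acid letters
#'   (`ACDEFGHIKLMNPQRSTVWY`).
#' @export
amino_acids <- function() {
  strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
}

#' The 64 codons in translation-table order
#'
#' First, second and third base each cycle through T, C, A, G (TTT, TTC,
#' TTA, TTG, TCT, ..., GGG), the order conventionally used to print genetic
#' code tables. DNA alphabet; use [code_string()] with `rna = TRUE` for an
#' RNA rendering.
#'
#' @return Character vector of 64 codons.
#' @export
codons <- function() {
  b <- c("T", "C", "A", "G")
  as.vector(vapply(b, function(x1)
    vapply(b, function(x2) paste0(x1, x2, b), character(4)),
    matrix("", 4, 4)))
}

#' Genetic code tables
#'
#' A genetic code is represented as a named character vector of length 64
#' mapping each codon (DNA alphabet, names in [codons()] order) to a single
#' amino acid letter, `"*"` for a stop codon, or `"?"` for a codon with no
#' single amino acid meaning. `standard_code()` returns the standard code;
#' `code_with()` derives an alternative code by reassigning individual
#' codons, e.g. `code_with(CTG = "S")` for the CUG-to-serine yeast code.
#'
#' @param code A genetic code vector to modify.
#' @param ... Named codon reassignments, e.g. `TGA = "W"`. RNA spellings
#'   (with U) are accepted.
#' @return Named character vector of length 64.
#' @examples
#' sc <- standard_code()
#' sc[["TGA"]] # "*"
#' code_with(TGA = "W")[["TGA"]]
#' @export
standard_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  out <- unname(gc[codons()])
  names(out) <- codons()
  out
}

#' @rdname standard_code
#' @export
code_with <- function(..., code = standard_code()) {
  mods <- c(...)
  if (length(mods) == 0) return(code)
  nm <- toupper(chartr("U", "T", names(mods)))
  bad <- setdiff(nm, codons())
  if (length(bad) > 0) {
    stop("not codons: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  ok <- mods %in% c(amino_acids(), "*", "?")
  if (!all(ok)) {
    stop("invalid code characters: ", paste(mods[!ok], collapse = ", "),
         call. = FALSE)
  }
  code[nm] <- unname(mods)
  code
}

#' Render a genetic code as a 64-character string
#'
#' @param code A genetic code vector (see [standard_code()]) or a fitted
#'   code from [infer_genetic_code()].
#' @param rna Display codon order identically but intended for RNA contexts;
#'   affects nothing in the string itself (codon order is fixed), provided
#'   for symmetry with [print()] methods.
#' @return A single string of 64 characters in [codons()] order.
#' @export
code_string <- function(code, rna = FALSE) {
  if (inherits(code, "genetic_code_fit")) {
    return(paste(code$aa[match(codons(), code$codon)], collapse = ""))
  }
  stopifnot(length(code) == 64)
  paste(code[codons()], collapse = "")
}

# vectorized codon -> character translation; codons not in the table
# (ambiguity codes, partials) give `unknown`; stop and '?' entries give
# `stop_char`/`unknown` respectively when requested
translate_codons <- function(cdn, code = standard_code(),
                             stop_char = "X", unknown_char = "X") {
  aa <- unname(code[cdn])
  aa[is.na(aa)] <- unknown_char
  aa[aa == "*"] <- stop_char
  aa[aa == "?"] <- unknown_char
  aa
}

# codons assigned to a given amino acid letter under `code`
codons_for <- function(aa, code = standard_code()) {
  names(code)[code == aa]
}
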