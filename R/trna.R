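#' @title Rule-based tRNA isotype classification from identity elements
#' @description Aminoacyl-tRNA synthetases recognize their cognate tRNAs
#'   through identity elements: the discriminator base N73, D-loop position
#'   N20, acceptor-stem base pairs, and anticodon-loop positions. These
#'   rules predict the charged amino acid of a tRNA gene from sequence
#'   alone, which is how the amino acid identity of codon-reassigning tRNAs
#'   is established. Position numbering follows the standard (Sprinzl)
#'   convention.
#' @name trna_identity
NULL

#' Parse a tRNA sequence/structure record into numbered positions
#'
#' Consumes a tRNAscan-SE-style pair of sequence and secondary structure
#' strings (structure uses `>`/`<` for paired bases, `.` for unpaired,
#' aligned 1:1 with the sequence) and resolves the numbered positions used
#' by the identity rules by walking the cloverleaf: acceptor stem (7 bp),
#' D-arm, anticodon arm, variable loop, T-arm, discriminator base.
#'
#' Position 20 in the D-loop is located by anchoring on the conserved
#' G18-G19 dinucleotide; when the D-loop is unusual (no unambiguous G18-G19
#' anchor, or an out-of-range loop length), `d_loop_usual` is set to
#' `FALSE` and downstream classification refuses to assign an isotype.
#'
#' @param seq tRNA gene sequence (DNA or RNA; T is read as U).
#' @param structure Secondary structure string of the same length.
#' @param id Record identifier.
#' @return A one-row tibble: `id`, `n1_72`, `n2_71`, `n3_70` (acceptor-stem
#'   pairs as `"G:C"`-style strings), `n10`, `n20`, `anticodon`, `n35`,
#'   `n37`, `n38`, `n73`, `var_loop_len`, `d_loop_usual`. Unresolvable
#'   positions are `NA`.
#' @export
parse_trna_record <- function(seq, structure, id = "trna") {
  s <- strsplit(toupper(chartr("T", "U", seq)), "")[[1]]
  st <- strsplit(structure, "")[[1]]
  if (length(s) != length(st)) {
    stop("structure string does not align 1:1 with sequence", call. = FALSE)
  }
  open <- which(st == ">")
  close <- which(st == "<")
  if (length(open) != length(close)) {
    stop("unalignable structure: unbalanced pairing brackets", call. = FALSE)
  }
  # pair map via stack
  stack <- integer(0)
  mate <- rep(NA_integer_, length(s))
  for (i in seq_along(st)) {
    if (st[i] == ">") stack <- c(stack, i)
    if (st[i] == "<") {
      if (length(stack) == 0) {
        stop("unalignable structure: unmatched '<'", call. = FALSE)
      }
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      mate[i] <- j
      mate[j] <- i
    }
  }
  # helices as maximal runs of consecutive '>' openings
  paired5 <- which(!is.na(mate) & st == ">")
  helix_id <- cumsum(c(TRUE, diff(paired5) != 1L |
                         mate[paired5][-1] != mate[paired5][-length(paired5)] - 1L))
  helices <- split(paired5, helix_id)
  if (length(helices) < 4) {
    stop("unalignable structure: fewer than four stems", call. = FALSE)
  }
  acceptor <- helices[[1]]
  d_stem <- helices[[2]]
  ac_stem <- helices[[3]]
  t_stem <- helices[[length(helices)]]
  pair_at <- function(i) {
    if (is.na(i) || is.na(mate[i])) return(NA_character_)
    paste0(s[i], ":", s[mate[i]])
  }
  n1_72 <- pair_at(acceptor[1])
  n2_71 <- pair_at(acceptor[2])
  n3_70 <- pair_at(acceptor[3])
  n10 <- s[d_stem[1]]
  # D-loop: unpaired stretch between the two halves of the D-stem
  d5_end <- d_stem[length(d_stem)]
  d3_start <- min(mate[d_stem])
  d_loop <- if (d3_start - d5_end > 1) s[(d5_end + 1):(d3_start - 1)] else
    character(0)
  dl <- length(d_loop)
  n20 <- NA_character_
  d_loop_usual <- TRUE
  if (dl < 5 || dl > 11) {
    d_loop_usual <- FALSE
  } else {
    # anchor on conserved G18-G19; candidate offsets allow 0 or 1 insertion
    # at position 17 (positions 14,15,16,(17,17a),18,19)
    gg <- which(d_loop[-dl] == "G" & d_loop[-1] == "G")
    gg <- gg[gg >= 4 & gg <= 6]
    if (length(gg) != 1) {
      d_loop_usual <- FALSE
    } else {
      after <- dl - (gg + 1)  # bases after G19: 20,(20a,20b),21
      if (after >= 2) n20 <- d_loop[gg + 2] else
        n20 <- "-"  # position 20 absent
      if (after < 1 || after > 4) d_loop_usual <- FALSE
    }
  }
  # anticodon loop: unpaired stretch inside the anticodon stem
  ac5_end <- ac_stem[length(ac_stem)]
  ac3_start <- min(mate[ac_stem])
  ac_loop <- s[(ac5_end + 1):(ac3_start - 1)]
  if (length(ac_loop) != 7) {
    stop("unalignable structure: anticodon loop is not 7 nt", call. = FALSE)
  }
  anticodon <- paste(ac_loop[3:5], collapse = "")
  n35 <- ac_loop[4]
  n37 <- ac_loop[6]
  n38 <- ac_loop[7]
  # variable loop: between the anticodon-stem 3' half and the T-stem
  ac3_end <- max(mate[ac_stem])
  var_loop_len <- t_stem[1] - ac3_end - 1L
  # discriminator: base after the acceptor-stem 3' half (before 3' CCA)
  acc3_end <- max(mate[acceptor])
  n73 <- if (acc3_end < length(s)) s[acc3_end + 1] else NA_character_
  tibble::tibble(id = id, n1_72 = n1_72, n2_71 = n2_71, n3_70 = n3_70,
                 n10 = n10, n20 = n20, anticodon = anticodon, n35 = n35,
                 n37 = n37, n38 = n38, n73 = n73,
                 var_loop_len = as.integer(var_loop_len),
                 d_loop_usual = d_loop_usual)
}

# is a 1:72-style pair weak? (A:U, U:A, G:U, U:G or a mismatch; G:C/C:G
# are strong)
is_weak_pair <- function(p) {
  if (is.na(p)) return(NA)
  !(p %in% c("G:C", "C:G"))
}

#' Identity-element rulesets
#'
#' Declarative required/support element maps per ruleset. Required elements
#' must all hold for an isotype call; support elements are reported but
#' never required. Element predicates: allowed bases at a position (`"A"`,
#' `"A/G"`), negation (`"!A"`, satisfied by a definite non-A base,
#' including an absent position), pair values (`"G:C"`), `"weak"` for a
#' weak 1:72 pair, and `">12"` for the variable-loop length.
#'
#' @return A named list of rulesets; each ruleset is an ordered list of
#'   isotypes with `required` and `support` element maps.
#' @export
trna_rulesets <- function() {
  path <- system.file("extdata", "trna_rulesets.yaml",
                      package = "codonscope")
  yaml::read_yaml(path)
}

# evaluate one element predicate against a record; TRUE/FALSE/NA (unknown)
eval_element <- function(rec, field, spec) {
  if (field == "var_loop_len") {
    thr <- as.numeric(sub(">", "", spec))
    return(rec$var_loop_len > thr)
  }
  val <- rec[[field]]
  if (is.na(val)) return(NA)
  if (field %in% c("n1_72", "n2_71", "n3_70") && spec == "weak") {
    return(is_weak_pair(val))
  }
  if (startsWith(spec, "!")) {
    return(!(val == sub("!", "", spec)))
  }
  allowed <- strsplit(spec, "/")[[1]]
  if (grepl(":", spec)) {
    return(val %in% allowed)
  }
  val %in% allowed
}

#' Classify the amino acid identity of a tRNA from identity elements
#'
#' Applies a clade-specific ruleset: the first isotype whose required
#' elements are all satisfied is returned, with satisfied support elements
#' reported alongside. Records whose D-loop was too unusual to locate N20
#' (`d_loop_usual == FALSE`), or with an unknown base at any required
#' position, are left `unassigned` -- the rules never guess.
#'
#' Available rulesets: `bacterial_arg_met` (Arg requires A20 with A/G73;
#' Met requires A73 and not A20, acceptor-stem pairs G2:C71/C3:G70 as
#' support), `bacterial_trp` (G73, not A20; A/G1:U72 support),
#' `bacterial_gln` (weak 1:72 pair, A37, A/G73, not A20; G2:C71, G3:C70,
#' G38, G10 support), `bacterial_gly` (G1:C72, C2:G71, G3:C70, U73), and
#' `yeast_ser_leu` (long variable loop >12 nt; Leu if A73 with A35 and
#' G37, otherwise Ser, with non-G73 serine calls flagged as reduced
#' confidence).
#'
#' @param records A tibble of tRNA records (rows as returned by
#'   [parse_trna_record()], or assembled directly from numbered positions).
#' @param ruleset Ruleset name (see above).
#' @param rulesets Rulesets definition; defaults to the packaged
#'   declarative config ([trna_rulesets()]).
#' @return A tibble: `id`, `isotype` (`Arg`, `Met`, `Trp`, `Gln`, `Gly`,
#'   `Ser`, `Leu`, or `unassigned`), `support_met` (satisfied support
#'   elements, comma-separated), `note`, `ruleset`.
#' @export
classify_isotype <- function(records, ruleset, rulesets = trna_rulesets()) {
  if (!ruleset %in% names(rulesets)) {
    stop("unknown ruleset '", ruleset, "'; available: ",
         paste(names(rulesets), collapse = ", "), call. = FALSE)
  }
  rs <- rulesets[[ruleset]]
  purrr::pmap_dfr(records, function(...) {
    rec <- tibble::tibble(...)
    call <- "unassigned"
    supp <- character(0)
    note <- ""
    uses_n20 <- any(vapply(rs, function(r) "n20" %in% names(r$required),
                           TRUE))
    if (isFALSE(rec$d_loop_usual) && uses_n20) {
      note <- "unusual D-loop: N20 ambiguous"
    } else {
      for (iso in names(rs)) {
        req <- rs[[iso]]$required
        ok <- vapply(names(req), function(f) eval_element(rec, f, req[[f]]),
                     TRUE)
        if (anyNA(ok)) next  # unknown at a required position: never guess
        if (all(ok)) {
          call <- iso
          sup <- rs[[iso]]$support
          if (!is.null(sup)) {
            sok <- vapply(names(sup),
                          function(f) eval_element(rec, f, sup[[f]]), TRUE)
            supp <- paste0(names(sup)[!is.na(sok) & sok], "=",
                           unlist(sup)[!is.na(sok) & sok])
          }
          flag <- rs[[iso]]$flag_if_not
          if (!is.null(flag)) {
            fok <- vapply(names(flag),
                          function(f) eval_element(rec, f, flag[[f]]), TRUE)
            if (any(is.na(fok) | !fok)) {
              note <- paste0("reduced confidence: ",
                             paste(names(flag)[is.na(fok) | !fok],
                                   collapse = ","), " atypical")
            }
          }
          break
        }
      }
    }
    tibble::tibble(id = rec$id, isotype = call,
                   support_met = paste(supp, collapse = ","),
                   note = note, ruleset = ruleset)
  })
}
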