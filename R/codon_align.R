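#' Codon alignment objects
#'
#' A codon alignment stores, per species, a gapped coding sequence whose
#' length is a multiple of three and whose columns correspond one-to-one to
#' the columns of the guiding protein alignment. It is the input expected by
#' the codon substitution model: every non-gap triplet must be a sense codon
#' (or contain IUPAC ambiguity codes, which are treated as missing data).
#'
#' @param sequences Named character vector, species -> gapped nucleotide
#'   string. All strings must have equal length divisible by 3.
#' @return An object of class `codon_alignment`: the named character vector
#'   with attributes `n_sites` (codon columns) and `species`.
#' @export
codon_alignment <- function(sequences) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences))) {
    abort("`sequences` must be uniquely named by species.")
  }
  sequences <- vapply(sequences, normalize_nt, character(1))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    abort("all rows of a codon alignment must have equal length.")
  }
  if (lens[1] %% 3L != 0L) {
    abort("codon alignment length must be a multiple of 3.")
  }
  structure(sequences,
            n_sites = lens[1] %/% 3L,
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d species x %d codon sites\n",
              length(x), attr(x, "n_sites")))
  invisible(x)
}

# species x site character matrix of codons (single-site alignments need
# the explicit matrix shape: vapply returns a bare vector for them)
codon_matrix <- function(caln) {
  n <- attr(caln, "n_sites")
  m <- vapply(unclass(caln), split_codons, character(n))
  if (n == 1L) {
    matrix(m, nrow = length(caln), ncol = 1L,
           dimnames = list(names(caln), NULL))
  } else {
    t(m)
  }
}

#' Back-translate a protein alignment into a codon alignment
#'
#' Re-implements the template-guided back-translation step (the PAL2NAL
#' idea): each aligned amino-acid row is replaced by the corresponding
#' codons of that species' unaligned CDS, with protein gaps expanded to gap
#' triplets (`---`). One terminal stop codon, if present, is stripped from
#' each CDS before length checking. The operation is strict: a CDS whose
#' length does not equal three times the ungapped protein length, a codon
#' that does not translate to its aligned residue, or an internal stop codon
#' is an error naming the offending species and position.
#'
#' @param aln Named character vector (or list), species -> gapped amino-acid
#'   string; all rows the same length. Gap character `-`.
#' @param cds Named character vector, species -> unaligned CDS (no gaps).
#'   Must cover every species in `aln`.
#' @return A [codon_alignment()].
#' @export
#' @examples
#' back_translate(c(sp1 = "M-K", sp2 = "MLK"),
#'                c(sp1 = "ATGAAA", sp2 = "ATGCTTAAG"))
back_translate <- function(aln, cds) {
  aln <- vapply(aln, toupper, character(1))
  if (is.null(names(aln))) abort("`aln` must be named by species.")
  missing <- setdiff(names(aln), names(cds))
  if (length(missing)) {
    abort(paste0("no CDS provided for species: ",
                 paste(missing, collapse = ", ")))
  }
  widths <- nchar(aln)
  if (length(unique(widths)) != 1L) {
    abort("protein alignment rows must all have the same length.")
  }
  out <- vapply(names(aln), function(sp) {
    prot <- strsplit(aln[[sp]], "")[[1]]
    nt <- normalize_nt(cds[[sp]])
    if (nchar(nt) %% 3L != 0L) {
      abort(sprintf("CDS of %s has length %d, not a multiple of 3.",
                    sp, nchar(nt)))
    }
    codons <- split_codons(nt)
    # strip one terminal stop if present
    if (length(codons) &&
        isTRUE(translate_codons(codons[length(codons)]) == "*")) {
      codons <- codons[-length(codons)]
    }
    n_res <- sum(prot != "-")
    if (length(codons) != n_res) {
      abort(sprintf(
        "CDS/protein length mismatch for %s: %d codons for %d residues.",
        sp, length(codons), n_res))
    }
    aa <- translate_codons(codons)
    stops <- which(aa == "*")
    if (length(stops)) {
      abort(sprintf("internal stop codon in %s at codon %d.", sp, stops[1]))
    }
    conflict <- which(!is.na(aa) & aa != prot[prot != "-"] &
                        prot[prot != "-"] != "X")
    if (length(conflict)) {
      k <- conflict[1]
      abort(sprintf(
        "codon %d of %s translates to %s but aligned residue is %s.",
        k, sp, aa[k], prot[prot != "-"][k]))
    }
    row <- rep("---", length(prot))
    row[prot != "-"] <- codons
    paste0(row, collapse = "")
  }, character(1))
  codon_alignment(out)
}

#' Validate a codon alignment for model fitting
#'
#' Report-only check of the invariants the branch-site likelihood relies
#' on: reading frame, absence of internal stop codons, and location of
#' ambiguity codes (which downstream code treats as missing data rather
#' than deleting the column).
#'
#' @param caln A [codon_alignment()].
#' @return A tibble with one row per finding: `species`, `site` (codon
#'   column, 1-based), `type` (`"internal_stop"`, `"invalid_codon"`, or
#'   `"ambiguous"`), `codon`. A clean alignment yields zero rows.
#' @export
validate_codon_alignment <- function(caln) {
  stopifnot(inherits(caln, "codon_alignment"))
  m <- codon_matrix(caln)
  rows <- list()
  for (sp in rownames(m)) {
    for (s in seq_len(ncol(m))) {
      cod <- m[sp, s]
      if (cod == "---") next
      if (grepl("^[ACGT]{3}$", cod)) {
        if (translate_codons(cod) == "*") {
          rows[[length(rows) + 1L]] <-
            tibble::tibble(species = sp, site = s,
                           type = "internal_stop", codon = cod)
        }
      } else if (length(codon_compatible_states(cod)) > 0L) {
        rows[[length(rows) + 1L]] <-
          tibble::tibble(species = sp, site = s,
                         type = "ambiguous", codon = cod)
      } else {
        rows[[length(rows) + 1L]] <-
          tibble::tibble(species = sp, site = s,
                         type = "invalid_codon", codon = cod)
      }
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(species = character(), site = integer(),
                          type = character(), codon = character()))
  }
  dplyr::bind_rows(rows)
}

#' Remove gaps from each row of a codon alignment
#'
#' @param caln A [codon_alignment()].
#' @return Named character vector of ungapped CDS sequences.
#' @export
degap_alignment <- function(caln) {
  vapply(unclass(caln), function(x) gsub("-", "", x, fixed = TRUE),
         character(1))
}
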