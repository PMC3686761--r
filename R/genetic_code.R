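#' The 61 sense codons of the standard genetic code
#'
#' Codon substitution models for positive-selection inference operate on the
#' 61 sense codons of the standard (table 1) genetic code; the three stop
#' codons (TAA, TAG, TGA) are excluded from the state space.
#'
#' @return Character vector of 61 codons, in the fixed state order used by
#'   all rate matrices and alignments in this package.
#' @export
#' @examples
#' length(sense_codons())
sense_codons <- function() {
  code_tables()$codons
}

#' Translate codons to amino acids (standard code)
#'
#' @param codons Character vector of codons (ACGT alphabet, uppercase).
#' @return Character vector of one-letter amino acids; `"*"` for stops,
#'   `NA` for codons containing non-ACGT characters.
#' @export
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  aa
}

# Build and cache the code tables: sense codon list, amino acid per codon,
# and the single-nucleotide-step neighbour structure (i, j, transition?,
# synonymous?) that defines the sparsity pattern of the rate matrix.
code_tables <- function() {
  if (!is.null(the$code)) {
    return(the$code)
  }
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  aa <- unname(gc[codons])
  n <- length(codons)
  stopifnot(n == 61L)
  cmat <- do.call(rbind, strsplit(codons, ""))
  idx <- seq_len(n)
  pairs_i <- integer(0)
  pairs_j <- integer(0)
  is_ts <- logical(0)
  is_syn <- logical(0)
  purine <- c(A = TRUE, G = TRUE, C = FALSE, T = FALSE)
  for (i in idx) {
    for (j in idx) {
      if (i == j) next
      diff <- cmat[i, ] != cmat[j, ]
      if (sum(diff) != 1L) next
      pos <- which(diff)
      pairs_i <- c(pairs_i, i)
      pairs_j <- c(pairs_j, j)
      is_ts <- c(is_ts, purine[cmat[i, pos]] == purine[cmat[j, pos]])
      is_syn <- c(is_syn, aa[i] == aa[j])
    }
  }
  the$code <- list(
    codons = codons, aa = aa, cmat = cmat,
    pairs = list(i = pairs_i, j = pairs_j,
                 transition = unname(is_ts), synonymous = unname(is_syn))
  )
  the$code
}

# Map a codon string (possibly with IUPAC ambiguity codes) to the indices of
# compatible sense codons. A gap triplet or fully ambiguous codon returns all
# 61 states (missing data). Cached per codon string.
codon_compatible_states <- function(codon) {
  if (is.null(the$compat)) the$compat <- new.env(parent = emptyenv())
  hit <- the$compat[[codon]]
  if (!is.null(hit)) {
    return(hit)
  }
  ct <- code_tables()
  n <- 61L
  if (codon == "---") {
    out <- seq_len(n)
  } else {
    iupac <- Biostrings::IUPAC_CODE_MAP
    chars <- strsplit(codon, "")[[1]]
    sets <- lapply(chars, function(ch) {
      if (ch %in% c("-", ".", "?")) c("A", "C", "G", "T")
      else if (ch %in% names(iupac)) strsplit(iupac[[ch]], "")[[1]]
      else character(0)
    })
    if (any(lengths(sets) == 0)) {
      out <- integer(0)
    } else {
      keep <- ct$cmat[, 1] %in% sets[[1]] &
        ct$cmat[, 2] %in% sets[[2]] &
        ct$cmat[, 3] %in% sets[[3]]
      out <- which(keep)
    }
  }
  the$compat[[codon]] <- out
  out
}

# Split a nucleotide string into codons; assumes length %% 3 == 0.
split_codons <- function(x) {
  substring(x, seq(1, nchar(x), by = 3), seq(3, nchar(x), by = 3))
}

# Uppercase + U->T normalization for nucleotide sequences.
normalize_nt <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}
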