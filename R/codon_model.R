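#' Estimate codon equilibrium frequencies (F3x4)
#'
#' The F3x4 convention estimates the equilibrium frequency of sense codon
#' xyz as the product of the empirical nucleotide frequencies at the three
#' codon positions, renormalized over the 61 sense codons. Gap triplets and
#' cells containing ambiguity codes contribute nothing to the counts.
#'
#' @param caln A [codon_alignment()].
#' @return A numeric vector of 61 frequencies (class `codon_frequencies`),
#'   named by codon, summing to 1, with attribute `position_freqs` (4x3
#'   nucleotide-by-position matrix) and attribute `zero_codons` listing
#'   sense codons assigned frequency 0 because a constituent nucleotide was
#'   never observed at that position.
#' @export
estimate_codon_frequencies_f3x4 <- function(caln) {
  m <- codon_matrix(caln)
  keep <- grepl("^[ACGT]{3}$", m)
  cods <- m[keep]
  nt <- c("A", "C", "G", "T")
  pos <- matrix(0, 4, 3, dimnames = list(nt, NULL))
  for (k in 1:3) {
    tab <- table(factor(substr(cods, k, k), levels = nt))
    tot <- sum(tab)
    pos[, k] <- if (tot > 0) as.numeric(tab) / tot else rep(0.25, 4)
  }
  ct <- code_tables()
  pi <- pos[ct$cmat[, 1], 1] * pos[ct$cmat[, 2], 2] * pos[ct$cmat[, 3], 3]
  names(pi) <- ct$codons
  if (sum(pi) <= 0) abort("alignment contains no countable codons.")
  pi <- pi / sum(pi)
  structure(pi,
            position_freqs = pos,
            zero_codons = ct$codons[pi == 0],
            class = "codon_frequencies")
}

#' Estimate codon equilibrium frequencies (F1x4)
#'
#' Like F3x4 but with a single nucleotide distribution pooled over the
#' three codon positions.
#'
#' @inheritParams estimate_codon_frequencies_f3x4
#' @return A `codon_frequencies` vector (61 frequencies summing to 1).
#' @export
estimate_codon_frequencies_f1x4 <- function(caln) {
  m <- codon_matrix(caln)
  cods <- m[grepl("^[ACGT]{3}$", m)]
  nt <- c("A", "C", "G", "T")
  chars <- unlist(strsplit(cods, ""), use.names = FALSE)
  tab <- table(factor(chars, levels = nt))
  f <- if (sum(tab) > 0) as.numeric(tab) / sum(tab) else rep(0.25, 4)
  names(f) <- nt
  ct <- code_tables()
  pi <- f[ct$cmat[, 1]] * f[ct$cmat[, 2]] * f[ct$cmat[, 3]]
  names(pi) <- ct$codons
  pi <- pi / sum(pi)
  structure(pi, nucleotide_freqs = f,
            zero_codons = ct$codons[pi == 0],
            class = "codon_frequencies")
}

#' Uniform codon frequencies (1/61)
#' @return A `codon_frequencies` vector with every sense codon at 1/61.
#' @export
equal_codon_frequencies <- function() {
  ct <- code_tables()
  structure(setNames(rep(1 / 61, 61), ct$codons),
            class = "codon_frequencies")
}

#' Build the 61x61 codon rate matrix
#'
#' Goldman-Yang-structured generator: substitutions changing more than one
#' codon position are forbidden; a single-position change i -> j has rate
#' `pi[j]`, multiplied by `kappa` if it is a transition and by `omega` if it
#' is nonsynonymous. The diagonal makes rows sum to zero. The matrix is
#' returned unscaled; rate normalization is applied at the mixture level by
#' the fitting and simulation code.
#'
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio dN/dS (>= 0).
#' @param pi Numeric vector of 61 codon frequencies.
#' @return 61x61 matrix `Q` with rows summing to 0, satisfying detailed
#'   balance `pi[i] Q[i,j] = pi[j] Q[j,i]`.
#' @export
build_rate_matrix <- function(kappa, omega, pi) {
  stopifnot(kappa > 0, omega >= 0, length(pi) == 61L)
  ct <- code_tables()
  p <- ct$pairs
  rate <- pi[p$j] * ifelse(p$transition, kappa, 1) *
    ifelse(p$synonymous, 1, omega)
  Q <- matrix(0, 61, 61, dimnames = list(ct$codons, ct$codons))
  Q[cbind(p$i, p$j)] <- rate
  diag(Q) <- -rowSums(Q)
  Q
}

#' Expected substitution rate of a generator at stationarity
#'
#' `-sum(pi * diag(Q))`: the flow rate used to normalize generators so
#' branch lengths read as expected substitutions per codon.
#'
#' @param Q Generator matrix.
#' @param pi Stationary codon frequencies.
#' @return Scalar expected rate.
#' @export
expected_rate <- function(Q, pi) {
  -sum(pi * diag(Q))
}

#' Transition probability matrix of a codon generator
#'
#' Computes `P(t) = expm(Q t)`. When the stationary distribution `pi` of a
#' reversible generator is supplied, a symmetric eigendecomposition is used
#' (fast and numerically stable); otherwise the computation falls back on
#' `ape::matexpo`.
#'
#' @param Q Generator matrix (rows sum to 0), already scaled as desired.
#' @param t Elapsed time (expected substitutions per codon), `t >= 0`.
#' @param pi Optional stationary distribution for the reversible fast path.
#' @return Stochastic matrix `P(t)` (rows sum to 1).
#' @export
transition_matrix <- function(Q, t, pi = NULL) {
  stopifnot(t >= 0)
  if (is.null(pi)) {
    return(ape::matexpo(Q * t))
  }
  eig <- rev_eigen_Q(Q, pi)
  pmat_from_eigen(eig, t)
}

# Symmetric eigendecomposition of a pi-reversible generator, restricted to
# states with pi > 0 (states with pi = 0 are unreachable and kept as
# absorbing identity rows when the matrix is embedded back).
rev_eigen_Q <- function(Q, pi) {
  act <- which(pi > 0)
  sq <- sqrt(pi[act])
  S <- Q[act, act, drop = FALSE] * outer(sq, 1 / sq)
  S <- (S + t(S)) / 2
  e <- eigen(S, symmetric = TRUE)
  list(left = e$vectors / sq,        # rows scaled by 1/sqrt(pi)
       right = t(e$vectors * sq),    # columns scaled by sqrt(pi)
       values = e$values,
       active = act)
}

# Eigendecomposition for given (kappa, omega, pi, scale): the workhorse of
# the likelihood engine. scale divides the generator so branch lengths are
# expected substitutions per codon under the fitted mixture. An optional
# cache environment memoizes decompositions of the unscaled generator per
# (kappa, omega) — scale only rescales the eigenvalues, handled at P time.
rev_eigen <- function(kappa, omega, pi, scale = 1, cache = NULL) {
  key <- NULL
  if (!is.null(cache)) {
    key <- sprintf("%.17g|%.17g", kappa, omega)
    hit <- cache[[key]]
    if (!is.null(hit)) {
      hit$values <- hit$values0 / scale
      return(hit)
    }
  }
  Q <- build_rate_matrix(kappa, omega, pi)
  eig <- rev_eigen_Q(Q, pi)
  eig$values0 <- eig$values
  if (!is.null(key)) cache[[key]] <- eig
  eig$values <- eig$values0 / scale
  eig
}

# Full 61x61 P(t) from an eigendecomposition (identity on inactive states).
# Tiny negative entries from roundoff are clamped only when requested (the
# likelihood path tolerates them; sampling and the public API do not).
pmat_from_eigen <- function(eig, t, clamp = TRUE) {
  Pa <- eig$left %*% (exp(eig$values * t) * eig$right)
  if (clamp) Pa[Pa < 0] <- 0
  if (length(eig$active) == 61L) {
    return(Pa)
  }
  P <- diag(61)
  P[eig$active, eig$active] <- Pa
  P
}
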