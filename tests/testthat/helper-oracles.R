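# Independent oracles used across the suite. These deliberately avoid the
# package's pruning machinery: transition matrices come from ape::matexpo
# and likelihoods from explicit enumeration of internal-node states.

oracle_pmat <- function(kappa, omega, pi, scale, t) {
  Q <- build_rate_matrix(kappa, omega, pi)
  ape::matexpo(Q / scale * t)
}

# Mixture scale identical in definition to the fitted model: class-weighted
# expected rate under each class's background omega.
oracle_scale <- function(kappa, params, pi) {
  r <- function(om) {
    Q <- build_rate_matrix(kappa, om, pi)
    -sum(pi * diag(Q))
  }
  (params$p0 + params$p2a) * r(params$omega0) +
    (params$p1 + params$p2b) * r(1)
}

# Per-site likelihood under a single (bg, fg) omega regime by summing over
# every assignment of states to internal nodes.
oracle_site_lik_regime <- function(m, tree, fg_edge, omega_bg, omega_fg,
                                   kappa, pi, scale) {
  ntip <- length(tree$tip.label)
  n_int <- tree$Nnode
  root <- ntip + 1L
  states_of <- function(codon) psgscan:::codon_compatible_states(codon)
  P_of <- lapply(seq_len(nrow(tree$edge)), function(e) {
    om <- if (e == fg_edge) omega_fg else omega_bg
    oracle_pmat(kappa, om, pi, scale, tree$edge.length[e])
  })
  grid <- as.matrix(expand.grid(rep(list(1:61), n_int)))
  col_of <- function(node) node - ntip
  n_sites <- ncol(m)
  out <- numeric(n_sites)
  for (s in seq_len(n_sites)) {
    prodv <- pi[grid[, col_of(root)]]
    for (e in seq_len(nrow(tree$edge))) {
      par <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      pstates <- grid[, col_of(par)]
      P <- P_of[[e]]
      if (child <= ntip) {
        st <- states_of(m[tree$tip.label[child], s])
        v <- rowSums(P[, st, drop = FALSE])
        prodv <- prodv * v[pstates]
      } else {
        prodv <- prodv * P[cbind(pstates, grid[, col_of(child)])]
      }
    }
    out[s] <- sum(prodv)
  }
  out
}

# Brute-force model A log-likelihood: the four-class mixture of the above.
oracle_model_a_loglik <- function(caln, lt, params, pi) {
  tree <- lt$tree
  fg_edge <- lt$foreground_edge
  pi <- as.numeric(pi)
  m <- psgscan:::codon_matrix(caln)
  scale <- oracle_scale(params$kappa, params, pi)
  regimes <- list(c(params$omega0, params$omega0),
                  c(1, 1),
                  c(params$omega0, params$omega2),
                  c(1, params$omega2))
  wts <- c(params$p0, params$p1, params$p2a, params$p2b)
  L <- 0
  for (k in 1:4) {
    if (wts[k] == 0) next
    L <- L + wts[k] * oracle_site_lik_regime(
      m, tree, fg_edge, regimes[[k]][1], regimes[[k]][2],
      params$kappa, pi, scale)
  }
  sum(log(L))
}

# Exact binomial upper-tail by direct pmf summation (choose/powers).
oracle_binom_upper <- function(obs, n, q) {
  if (obs <= 0) return(1)
  k <- obs:n
  sum(choose(n, k) * q^k * (1 - q)^(n - k))
}

# Rooted-triple topology of three tips: returns the tip pair that forms
# the cherry, via pairwise path distances on the topology (unit lengths).
oracle_rooted_triple <- function(tree, tips) {
  tr <- ape::keep.tip(tree, tips)
  tr$edge.length <- rep(1, nrow(tr$edge))
  d <- ape::cophenetic.phylo(tr)[tips, tips]
  pairs <- utils::combn(tips, 2, simplify = FALSE)
  dd <- vapply(pairs, function(p) d[p[1], p[2]], numeric(1))
  paste(sort(pairs[[which.min(dd)]]), collapse = "|")
}

# Random codon alignment (unambiguous sense codons) for n species.
random_codon_alignment <- function(species, n_sites) {
  codons <- sense_codons()
  seqs <- vapply(species, function(s) {
    paste0(sample(codons, n_sites, replace = TRUE), collapse = "")
  }, character(1))
  codon_alignment(seqs)
}

# Random rooted binary tree with branch lengths in [0.05, 0.4].
random_tree <- function(n, tips = paste0("t", seq_len(n))) {
  tr <- ape::rtree(n, tip.label = tips)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.4)
  tr
}
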