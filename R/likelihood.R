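#' Branch-site model A parameter set
#'
#' Model A mixes four site classes. Classes 0 and 1 evolve with dN/dS
#' `omega0` (purifying, 0 <= omega0 <= 1) and 1 (neutral) on every branch;
#' classes 2a and 2b share the background behaviour of classes 0 and 1 but
#' switch to `omega2` on the foreground branch. Class proportions are
#' `p0`, `p1` for classes 0/1; the remainder `1 - p0 - p1` is split between
#' 2a and 2b in proportion `p0 : p1`.
#'
#' @param kappa Transition/transversion ratio (> 0).
#' @param omega0 Background purifying dN/dS, in `[0, 1]`.
#' @param omega2 Foreground dN/dS for classes 2a/2b (>= 1 under the
#'   alternative; the null fixes it at 1).
#' @param p0,p1 Proportions of classes 0 and 1 (`p0 + p1 <= 1`, `p0+p1 > 0`).
#' @return List of class `branch_site_params` including derived `p2a`,
#'   `p2b`.
#' @export
branch_site_params <- function(kappa, omega0, omega2, p0, p1) {
  stopifnot(kappa > 0, omega0 >= 0, omega0 <= 1, omega2 >= 0,
            p0 >= 0, p1 >= 0, p0 + p1 <= 1 + 1e-12)
  if (p0 + p1 <= 0) abort("p0 + p1 must be positive.")
  rest <- max(0, 1 - p0 - p1)
  structure(list(kappa = kappa, omega0 = omega0, omega2 = omega2,
                 p0 = p0, p1 = p1,
                 p2a = rest * p0 / (p0 + p1),
                 p2b = rest * p1 / (p0 + p1)),
            class = "branch_site_params")
}

# Per-class (background, foreground) omega map of model A.
class_omegas <- function(params) {
  with(params, list(
    `0`  = c(bg = omega0, fg = omega0),
    `1`  = c(bg = 1, fg = 1),
    `2a` = c(bg = omega0, fg = omega2),
    `2b` = c(bg = 1, fg = omega2)
  ))
}

# ---------------------------------------------------------------------------
# Data preparation: compress a codon alignment against a tree into site
# patterns with weights, per-tip state vectors, and postorder traversal
# bookkeeping used by the pruning passes.
bs_prepare <- function(caln, tree) {
  fg_edge_child <- NULL
  if (inherits(tree, "labeled_tree")) {
    fg_edge_child <- tree$tree$edge[tree$foreground_edge, 2]
    tree <- tree$tree
  }
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) {
    abort("tree must carry branch lengths (estimate them first, e.g. M0).")
  }
  m <- codon_matrix(caln)
  missing <- setdiff(tree$tip.label, rownames(m))
  if (length(missing)) {
    abort(paste0("alignment lacks species present in the tree: ",
                 paste(missing, collapse = ", ")))
  }
  m <- m[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)

  key <- apply(m, 2, paste, collapse = "|")
  upat <- !duplicated(key)
  pattern_of_site <- match(key, key[upat])
  weights <- tabulate(pattern_of_site, nbins = sum(upat))
  pm <- m[, upat, drop = FALSE]
  npat <- ncol(pm)

  tip_state <- vector("list", ntip)
  tip_amb <- vector("list", ntip)
  for (i in seq_len(ntip)) {
    cods <- pm[i, ]
    uc <- unique(cods)
    states <- lapply(uc, codon_compatible_states)
    ns <- lengths(states)
    if (any(ns == 0L)) {
      abort(sprintf("invalid codon '%s' for species %s.",
                    uc[which(ns == 0L)[1]], tree$tip.label[i]))
    }
    idx <- match(cods, uc)
    ust <- ifelse(ns[idx] == 1L,
                  vapply(states, `[`, integer(1), 1)[idx], NA_integer_)
    amb_cols <- which(is.na(ust))
    amb_part <- NULL
    if (length(amb_cols)) {
      amb_part <- matrix(0, 61, length(amb_cols))
      for (k in seq_along(amb_cols)) {
        amb_part[states[[idx[amb_cols[k]]]], k] <- 1
      }
    }
    filled <- ust
    if (length(amb_cols)) filled[amb_cols] <- 1L
    tip_state[[i]] <- ust
    tip_amb[[i]] <- list(cols = amb_cols, partial = amb_part,
                         filled = filled)
  }

  tr <- ape::reorder.phylo(tree, "postorder")
  edge <- tr$edge
  nedge <- nrow(edge)
  nnode_total <- ntip + tr$Nnode
  node_child_edges <- vector("list", nnode_total)
  parent_edge <- rep(NA_integer_, nnode_total)
  for (e in seq_len(nedge)) {
    p <- edge[e, 1]; ch <- edge[e, 2]
    node_child_edges[[p]] <- c(node_child_edges[[p]], e)
    parent_edge[ch] <- e
  }
  root <- ntip + 1L
  fg_edge <- if (is.null(fg_edge_child)) NULL
             else which(edge[, 2] == fg_edge_child)

  list(ntip = ntip, tips = tree$tip.label, root = root,
       edge = edge, nedge = nedge, edge_len = tr$edge.length,
       node_child_edges = node_child_edges, parent_edge = parent_edge,
       fg_edge = fg_edge,
       npat = npat, weights = weights, pattern_of_site = pattern_of_site,
       tip_state = tip_state, tip_amb = tip_amb,
       n_sites = length(key))
}

# Contribution of a tip's edge: P columns for unambiguous codons, a matmul
# against the indicator partial for ambiguous/missing cells.
leaf_contrib <- function(prep, tip, P) {
  amb <- prep$tip_amb[[tip]]
  C <- P[, amb$filled, drop = FALSE]
  if (length(amb$cols)) {
    C[, amb$cols] <- P %*% amb$partial
  }
  C
}

# One full postorder pruning pass with a single eigendecomposition applied
# to every edge. Returns per-edge contributions, per-node partials, the
# per-edge P matrices, and per-pattern site likelihoods.
prune_pass <- function(prep, eig, pi, edge_len = prep$edge_len) {
  partial <- vector("list", length(prep$node_child_edges))
  C <- vector("list", prep$nedge)
  Plist <- vector("list", prep$nedge)
  for (e in seq_len(prep$nedge)) {
    P <- pmat_from_eigen(eig, edge_len[e], clamp = FALSE)
    Plist[[e]] <- P
    child <- prep$edge[e, 2]
    C[[e]] <- if (child <= prep$ntip) leaf_contrib(prep, child, P)
              else P %*% partial[[child]]
    par <- prep$edge[e, 1]
    partial[[par]] <- if (is.null(partial[[par]])) C[[e]]
                      else partial[[par]] * C[[e]]
  }
  siteL <- drop(crossprod(pi, partial[[prep$root]]))
  list(C = C, partial = partial, P = Plist, siteL = siteL)
}

# Site likelihoods after swapping the foreground edge's rate regime: reuse
# the background pass and recompute only the foreground edge's contribution
# and its ancestors on the path to the root.
swap_foreground <- function(prep, pass, P_fg, pi) {
  e <- prep$fg_edge
  child <- prep$edge[e, 2]
  Cnew <- if (child <= prep$ntip) leaf_contrib(prep, child, P_fg)
          else P_fg %*% pass$partial[[child]]
  node <- prep$edge[e, 1]
  updated_edge <- e
  repeat {
    ce <- prep$node_child_edges[[node]]
    part <- Cnew
    for (k in ce) {
      if (k != updated_edge) part <- part * pass$C[[k]]
    }
    if (node == prep$root) {
      return(drop(crossprod(pi, part)))
    }
    eup <- prep$parent_edge[node]
    Cnew <- pass$P[[eup]] %*% part
    updated_edge <- eup
    node <- prep$edge[eup, 1]
  }
}

# Expected substitution rate of the unscaled generator, linear in omega for
# fixed kappa: r = syn_tv + kappa*syn_ts + omega*(nsyn_tv + kappa*nsyn_ts).
rate_components <- function(pi) {
  p <- code_tables()$pairs
  flux <- pi[p$i] * pi[p$j]
  c(syn_tv = sum(flux[p$synonymous & !p$transition]),
    syn_ts = sum(flux[p$synonymous & p$transition]),
    nsyn_tv = sum(flux[!p$synonymous & !p$transition]),
    nsyn_ts = sum(flux[!p$synonymous & p$transition]))
}

unscaled_rate <- function(rc, kappa, omega) {
  unname(rc["syn_tv"] + kappa * rc["syn_ts"] +
           omega * (rc["nsyn_tv"] + kappa * rc["nsyn_ts"]))
}

# Mixture-level scale factor: expected substitutions per codon per unit
# branch length, averaged over site classes with each class's background
# omega (the regime carried by all but the single foreground branch).
mixture_scale <- function(rc, kappa, omega0, p0, p1, p2a, p2b) {
  (p0 + p2a) * unscaled_rate(rc, kappa, omega0) +
    (p1 + p2b) * unscaled_rate(rc, kappa, 1)
}

# Core mixture log-likelihood used by fitting, simulation checks and the
# public wrapper. Two full passes (background omega0 and 1) plus foreground
# swaps for classes 2a/2b. An optional cache environment (one per fit)
# memoizes eigendecompositions per (kappa, omega) and the two background
# passes per (kappa, omega0, rho), so optimizer steps that only move
# omega2 skip the expensive full passes.
bs_loglik_engine <- function(prep, kappa, omega0, omega2, p0, p1, pi,
                             edge_len = prep$edge_len, cache = NULL) {
  params <- branch_site_params(kappa, omega0, omega2, p0, p1)
  rc <- rate_components(pi)
  rho <- mixture_scale(rc, kappa, omega0, p0, p1, params$p2a, params$p2b)
  key0 <- sprintf("%.17g|%.17g|%.17g", kappa, omega0, rho)
  key1 <- sprintf("%.17g|%.17g", kappa, rho)
  pass0 <- pass1 <- NULL
  if (!is.null(cache)) {
    if (identical(cache$pass0_key, key0)) pass0 <- cache$pass0
    if (identical(cache$pass1_key, key1)) pass1 <- cache$pass1
  }
  if (is.null(pass0)) {
    eig0 <- rev_eigen(kappa, omega0, pi, rho, cache)
    pass0 <- prune_pass(prep, eig0, pi, edge_len)
    if (!is.null(cache)) {
      cache$pass0 <- pass0
      cache$pass0_key <- key0
    }
  }
  if (is.null(pass1)) {
    eig1 <- rev_eigen(kappa, 1, pi, rho, cache)
    pass1 <- prune_pass(prep, eig1, pi, edge_len)
    if (!is.null(cache)) {
      cache$pass1 <- pass1
      cache$pass1_key <- key1
    }
  }
  L <- params$p0 * pass0$siteL + params$p1 * pass1$siteL
  if (params$p2a + params$p2b > 0) {
    if (is.null(prep$fg_edge)) {
      abort("classes 2a/2b need a tree with a foreground branch.")
    }
    eig2 <- rev_eigen(kappa, omega2, pi, rho, cache)
    P_fg <- pmat_from_eigen(eig2, edge_len[prep$fg_edge], clamp = FALSE)
    L <- L + params$p2a * swap_foreground(prep, pass0, P_fg, pi) +
      params$p2b * swap_foreground(prep, pass1, P_fg, pi)
  }
  sum(prep$weights * log(pmax(L, 1e-300)))
}

# One-ratio (M0) log-likelihood: a single omega on all branches.
m0_loglik_engine <- function(prep, kappa, omega, pi,
                             edge_len = prep$edge_len) {
  rc <- rate_components(pi)
  rho <- unscaled_rate(rc, kappa, omega)
  eig <- rev_eigen(kappa, omega, pi, rho)
  pass <- prune_pass(prep, eig, pi, edge_len)
  sum(prep$weights * log(pmax(pass$siteL, 1e-300)))
}

#' Log-likelihood of a codon alignment under branch-site model A
#'
#' Computes the pruning (Felsenstein) log-likelihood of an alignment on a
#' foreground-labeled tree under the four-class branch-site mixture. Gap
#' and ambiguous codons contribute a partial likelihood of one over all
#' compatible states (missing data). Branch lengths are interpreted as
#' expected substitutions per codon under the mixture-averaged background
#' rate.
#'
#' @param caln A [codon_alignment()].
#' @param tree A [label_foreground()] tree with branch lengths.
#' @param params A [branch_site_params()] set.
#' @param pi Codon frequencies; defaults to F3x4 estimated from `caln`.
#' @return The log-likelihood (scalar).
#' @export
model_a_loglik <- function(caln, tree, params, pi = NULL) {
  stopifnot(inherits(params, "branch_site_params"))
  if (is.null(pi)) pi <- estimate_codon_frequencies_f3x4(caln)
  prep <- bs_prepare(caln, tree)
  bs_loglik_engine(prep, params$kappa, params$omega0, params$omega2,
                   params$p0, params$p1, as.numeric(pi))
}
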