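#' Simulate a codon alignment under the branch-site model
#'
#' Generative counterpart of model A: each site draws a class from
#' `(p0, p1, p2a, p2b)`, the root codon is drawn from `pi`, and every
#' branch evolves the codon by sampling the child state directly from the
#' transition matrix `P(t)` built with that branch's class-appropriate
#' omega (foreground vs background). The generator is scaled exactly as in
#' fitting, so branch lengths mean expected substitutions per codon under
#' the mixture-averaged background rate. Replaying the same seed reproduces
#' the alignment byte-for-byte.
#'
#' @param tree A [label_foreground()] tree with branch lengths.
#' @param params A [branch_site_params()] set (the truth).
#' @param pi Codon frequencies (default uniform 1/61).
#' @param n_sites Number of codon sites (>= 1).
#' @param seed Integer seed; the function is a pure function of its
#'   arguments and the seed (caller RNG state is untouched).
#' @return List with `alignment` (a [codon_alignment()]) and `manifest`
#'   (list: `seed`, `params`, `pi`, `tree`, and `site_classes`, a tibble of
#'   per-site true class labels).
#' @export
simulate_codon_alignment <- function(tree, params, pi = NULL,
                                     n_sites, seed) {
  stopifnot(inherits(tree, "labeled_tree"),
            inherits(params, "branch_site_params"), n_sites >= 1)
  if (is.null(pi)) pi <- equal_codon_frequencies()
  pi_num <- as.numeric(pi)
  tr <- ape::reorder.phylo(tree$tree, "postorder")
  if (is.null(tr$edge.length)) abort("tree must carry branch lengths.")
  fg_child <- tree$tree$edge[tree$foreground_edge, 2]
  fg_edge <- which(tr$edge[, 2] == fg_child)
  ntip <- length(tr$tip.label)

  rc <- rate_components(pi_num)
  rho <- mixture_scale(rc, params$kappa, params$omega0,
                       params$p0, params$p1, params$p2a, params$p2b)
  omegas <- c(`0` = params$omega0, `1` = 1,
              `2a` = params$omega0, `2b` = 1)      # background regimes
  fg_omegas <- c(`0` = params$omega0, `1` = 1,
                 `2a` = params$omega2, `2b` = params$omega2)
  eig_of <- list()
  eig_for <- function(om) {
    key <- sprintf("%.12g", om)
    if (is.null(eig_of[[key]])) {
      eig_of[[key]] <<- rev_eigen(params$kappa, om, pi_num, rho)
    }
    eig_of[[key]]
  }

  withr::with_seed(seed, {
    classes <- sample(c("0", "1", "2a", "2b"), n_sites, replace = TRUE,
                      prob = c(params$p0, params$p1, params$p2a,
                               params$p2b))
    states <- matrix(NA_integer_, ntip + tr$Nnode, n_sites)
    root <- ntip + 1L
    states[root, ] <- sample.int(61L, n_sites, replace = TRUE,
                                 prob = pi_num)
    # preorder: walk edges from the root down
    for (e in rev(seq_len(nrow(tr$edge)))) {
      par <- tr$edge[e, 1]; child <- tr$edge[e, 2]
      t_e <- tr$edge.length[e]
      for (cl in unique(classes)) {
        om <- if (e == fg_edge) fg_omegas[[cl]] else omegas[[cl]]
        P <- pmat_from_eigen(eig_for(om), t_e)
        idx <- which(classes == cl)
        par_states <- states[par, idx]
        for (s in unique(par_states)) {
          sel <- idx[par_states == s]
          states[child, sel] <- sample.int(61L, length(sel),
                                           replace = TRUE, prob = P[s, ])
        }
      }
    }
    codons <- sense_codons()
    seqs <- vapply(seq_len(ntip), function(i) {
      paste0(codons[states[i, ]], collapse = "")
    }, character(1))
    names(seqs) <- tr$tip.label
    list(alignment = codon_alignment(seqs),
         manifest = list(seed = seed, params = params, pi = pi,
                         tree = tree,
                         site_classes = tibble::tibble(
                           site = seq_len(n_sites), class = classes)))
  })
}

#' Simulate an ortholog-group collection with controlled species composition
#'
#' Emulates the input of a genome scan: `n_groups` ortholog groups, each
#' containing a fixed required species set (the always-present lineages of
#' interest) plus a random subset of the remaining species pool, with the
#' total group size drawn from `size_distribution`. Sequences are random
#' sense-codon CDS of `n_codons` codons with their faithful translations —
#' composition and filtering behaviour, not phylogeny, is what this
#' generator exercises.
#'
#' @param species_pool Character vector of all candidate species.
#' @param required_species Subset of `species_pool` present in every group.
#' @param size_distribution Either an integer vector to sample group sizes
#'   from (with replacement) or a `function(n)` returning `n` sizes. The
#'   default mimics mammalian genome-scan collections: sizes 10-33 with
#'   most groups between 27 and 33 (a discretized normal, mean 28, sd 4).
#' @param n_groups Number of groups.
#' @param n_codons Codons per sequence (default 150).
#' @param seed Integer seed.
#' @return List with `groups` (an [ortholog_groups()] tibble) and `truth`
#'   (tibble: `group_id`, `n_species`).
#' @export
simulate_group_collection <- function(species_pool, required_species,
                                      size_distribution = NULL,
                                      n_groups, n_codons = 150, seed) {
  stopifnot(all(required_species %in% species_pool))
  nreq <- length(required_species)
  if (is.null(size_distribution)) {
    size_distribution <- function(n) {
      pmin(pmax(round(stats::rnorm(n, 28, 4)), 10L),
           min(33L, length(species_pool)))
    }
  }
  draw_sizes <- if (is.function(size_distribution)) {
    size_distribution
  } else {
    function(n) sample(as.integer(size_distribution), n, replace = TRUE)
  }
  codons <- sense_codons()
  withr::with_seed(seed, {
    sizes <- pmax(draw_sizes(n_groups), nreq)
    sizes <- pmin(sizes, length(species_pool))
    extras <- setdiff(species_pool, required_species)
    members <- lapply(seq_len(n_groups), function(k) {
      sp <- c(required_species,
              sample(extras, sizes[k] - nreq, replace = FALSE))
      cds <- vapply(sp, function(s) {
        paste0(sample(codons, n_codons, replace = TRUE), collapse = "")
      }, character(1))
      prot <- vapply(cds, function(x) {
        paste0(translate_codons(split_codons(x)), collapse = "")
      }, character(1))
      tibble::tibble(species = sp, protein = unname(prot),
                     cds = unname(cds))
    })
    ids <- sprintf("OG%05d", seq_len(n_groups))
    list(groups = ortholog_groups(ids, members),
         truth = tibble::tibble(group_id = ids, n_species = sizes))
  })
}

#' Simulate gene annotations with planted category enrichment
#'
#' Generates a flat annotation table over `categories`, assigns each gene
#' to each category with probability `baseline_rate`, and selects a PSG set
#' of size `round(psg_fraction * n_genes)` by weighted sampling in which
#' genes annotated to a planted category carry weight `fold` (fold = 1
#' plants nothing). The result feeds [binomial_enrichment()] with a flat
#' DAG built from the categories.
#'
#' @param genes Character vector of gene ids, or an integer count.
#' @param categories Character vector of category ids, or an integer count.
#' @param baseline_rate Per-(gene, category) annotation probability.
#' @param planted Named numeric vector: category id -> fold (>= 1); may be
#'   empty.
#' @param psg_fraction Fraction of genes selected as PSGs.
#' @param seed Integer seed.
#' @return List with `annotations` (tibble `gene`, `term`), `dag` (a flat
#'   [go_dag()]), `psg` (character vector), `reference` (all genes) and
#'   `truth` (tibble `category`, `fold`).
#' @export
simulate_annotations <- function(genes, categories, baseline_rate = 0.04,
                                 planted = numeric(), psg_fraction = 0.05,
                                 seed) {
  if (is.numeric(genes) && length(genes) == 1L) {
    genes <- sprintf("gene%05d", seq_len(genes))
  }
  if (is.numeric(categories) && length(categories) == 1L) {
    categories <- sprintf("GO:%07d", seq_len(categories))
  }
  if (length(planted)) {
    stopifnot(!is.null(names(planted)), all(planted >= 1),
              all(names(planted) %in% categories))
  }
  withr::with_seed(seed, {
    ann <- purrr::map_dfr(categories, function(cat) {
      hit <- runif(length(genes)) < baseline_rate
      tibble::tibble(gene = genes[hit], term = cat)
    })
    w <- rep(1, length(genes))
    names(w) <- genes
    for (cat in names(planted)) {
      in_cat <- unique(ann$gene[ann$term == cat])
      w[in_cat] <- w[in_cat] * planted[[cat]]
    }
    n_psg <- max(1L, round(psg_fraction * length(genes)))
    psg <- sample(genes, n_psg, replace = FALSE, prob = w)
    dag <- go_dag(parents = setNames(vector("list", length(categories)),
                                     categories),
                  names = setNames(categories, categories))
    list(annotations = ann, dag = dag, psg = sort(psg),
         reference = genes,
         truth = tibble::tibble(
           category = categories,
           fold = ifelse(categories %in% names(planted),
                         planted[categories], 1)))
  })
}
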