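#' Gene Ontology DAG objects
#'
#' A minimal GO DAG: for each term, its `is_a` parents (and optionally
#' `part_of` parents, traversed only on request). Must be acyclic; every
#' referenced parent must exist.
#'
#' @param parents Named list, term -> character vector of is_a parents.
#' @param names Named character vector, term -> human-readable name.
#' @param part_of Named list, term -> character vector of part_of parents.
#' @return Object of class `go_dag`.
#' @export
go_dag <- function(parents, names = NULL, part_of = NULL) {
  terms <- base::names(parents)
  if (is.null(terms)) abort("`parents` must be a named list.")
  parents <- lapply(parents, function(p) as.character(p %||% character()))
  base::names(parents) <- terms
  refd <- unique(unlist(parents, use.names = FALSE))
  unknown <- setdiff(refd, terms)
  if (length(unknown)) {
    abort(paste0("parents reference unknown terms: ",
                 paste(head(unknown, 5), collapse = ", ")))
  }
  structure(list(parents = parents,
                 names = names %||% setNames(terms, terms),
                 part_of = part_of %||% list()),
            class = "go_dag")
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms, %d is_a edges\n",
              length(x$parents), sum(lengths(x$parents))))
  invisible(x)
}

#' Read a GO DAG from an OBO file
#'
#' Parses `[Term]` stanzas: `id`, `name`, `is_a` and (optionally)
#' `relationship: part_of` lines; obsolete terms are skipped. This is a
#' deliberately small reader covering the subset of OBO needed for slim
#' mapping and enrichment.
#'
#' @param file Path to an OBO file.
#' @return A [go_dag()].
#' @export
read_obo <- function(file) {
  lines <- readLines(file, warn = FALSE)
  term_starts <- which(lines == "[Term]")
  parents <- list()
  nm <- character()
  part_of <- list()
  bounds <- c(term_starts, length(lines) + 1L)
  for (k in seq_along(term_starts)) {
    chunk <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    stop_at <- grep("^\\[", chunk)
    if (length(stop_at)) chunk <- chunk[seq_len(stop_at[1] - 1L)]
    get1 <- function(tag) {
      hit <- grep(paste0("^", tag, ": "), chunk, value = TRUE)
      sub(paste0("^", tag, ": "), "", hit)
    }
    if (any(grepl("^is_obsolete: true", chunk))) next
    id <- get1("id")[1]
    if (is.na(id) || !nzchar(id)) next
    isa <- sub(" !.*$", "", get1("is_a"))
    po <- grep("^relationship: part_of ", chunk, value = TRUE)
    po <- sub(" !.*$", "", sub("^relationship: part_of ", "", po))
    parents[[id]] <- trimws(isa)
    if (length(po)) part_of[[id]] <- trimws(po)
    n1 <- get1("name")[1]
    nm[id] <- if (is.na(n1)) id else n1
  }
  # drop dangling parent references (terms outside the file) with a note
  known <- names(parents)
  parents <- lapply(parents, function(p) intersect(p, known))
  part_of <- lapply(part_of, function(p) intersect(p, known))
  go_dag(parents, nm, part_of)
}

# Ancestor closure (term itself excluded) following is_a and, optionally,
# part_of edges; memoized within one call.
go_ancestors_all <- function(dag, terms, use_part_of = FALSE) {
  memo <- new.env(parent = emptyenv())
  up <- function(term) {
    hit <- memo[[term]]
    if (!is.null(hit)) {
      return(hit)
    }
    memo[[term]] <- character()   # cycle guard; DAG assumed acyclic
    par <- dag$parents[[term]]
    if (use_part_of) par <- union(par, dag$part_of[[term]])
    anc <- par
    for (p in par) anc <- union(anc, up(p))
    memo[[term]] <- anc
    anc
  }
  setNames(lapply(terms, up), terms)
}

#' Ancestors of a GO term
#' @param dag A [go_dag()].
#' @param term A term id.
#' @param use_part_of Also traverse part_of edges?
#' @return Character vector of ancestor term ids (term itself excluded).
#' @export
go_ancestors <- function(dag, term, use_part_of = FALSE) {
  if (!term %in% names(dag$parents)) abort(sprintf("unknown term %s", term))
  go_ancestors_all(dag, term, use_part_of)[[1]]
}

# Normalize annotations (tibble gene/term or named list gene -> terms) to a
# long tibble, dropping terms unknown to the DAG with a message.
normalize_annotations <- function(annotations, dag, quiet = FALSE) {
  if (!is.data.frame(annotations)) {
    annotations <- tibble::tibble(
      gene = rep(names(annotations), lengths(annotations)),
      term = unlist(annotations, use.names = FALSE))
  }
  stopifnot(all(c("gene", "term") %in% names(annotations)))
  unknown <- setdiff(unique(annotations$term), names(dag$parents))
  if (length(unknown)) {
    if (!quiet) {
      inform(sprintf("dropping %d annotation terms absent from the DAG.",
                     length(unknown)))
    }
    annotations <- annotations[!annotations$term %in% unknown, ,
                               drop = FALSE]
  }
  dplyr::distinct(annotations, .data$gene, .data$term)
}

# For each gene, which of `categories` does it hit (annotated to the
# category or to a descendant)? Returns a long tibble gene/category.
gene_category_hits <- function(annotations, dag, categories,
                               use_part_of = FALSE) {
  ann <- normalize_annotations(annotations, dag)
  terms <- unique(ann$term)
  anc <- go_ancestors_all(dag, terms, use_part_of)
  self_plus <- lapply(terms, function(tm) {
    intersect(c(tm, anc[[tm]]), categories)
  })
  names(self_plus) <- terms
  hits <- tibble::tibble(
    gene = rep(ann$gene, lengths(self_plus[ann$term])),
    category = unlist(self_plus[ann$term], use.names = FALSE))
  dplyr::distinct(hits, .data$gene, .data$category)
}

#' Map gene annotations onto a GO slim
#'
#' CateGOrizer-style classification: a gene hits a slim term if any of its
#' annotated terms equals the slim term or has it among its ancestors; each
#' (gene, slim term) pair counts once.
#'
#' @param annotations Tibble with columns `gene`, `term`, or a named list
#'   gene -> character vector of terms.
#' @param dag A [go_dag()].
#' @param slim Character vector of slim term ids (subset of the DAG).
#' @param use_part_of Also traverse part_of edges?
#' @return Tibble `term`, `name`, `n_genes`, one row per slim term with at
#'   least one hit, sorted by decreasing `n_genes`.
#' @export
map_to_slim_counts <- function(annotations, dag, slim,
                               use_part_of = FALSE) {
  bad <- setdiff(slim, names(dag$parents))
  if (length(bad)) {
    abort(paste0("slim terms not in DAG: ", paste(bad, collapse = ", ")))
  }
  if (!length(slim)) {
    return(tibble::tibble(term = character(), name = character(),
                          n_genes = integer()))
  }
  hits <- gene_category_hits(annotations, dag, slim, use_part_of)
  counts <- dplyr::count(hits, .data$category, name = "n_genes")
  tibble::tibble(term = counts$category,
                 name = unname(dag$names[counts$category]),
                 n_genes = counts$n_genes) |>
    dplyr::arrange(dplyr::desc(.data$n_genes), .data$term)
}

#' Binomial overrepresentation test of PSGs against the analyzed reference
#'
#' Panther-style enrichment: for each category with at least one annotated
#' reference gene, the number of PSGs hitting the category is compared with
#' a binomial expectation `n_category * |psg| / |reference|`. The raw
#' one-sided (overrepresentation) p-value is the binomial upper tail; the
#' Bonferroni factor `m` is the number of categories tested. Unannotated
#' genes stay in the denominators (whole-list fractions).
#'
#' @param psg Character vector of positively selected genes (must be a
#'   subset of `reference`).
#' @param reference Character vector of all analyzed genes.
#' @param annotations Tibble `gene`/`term` or named list.
#' @param dag A [go_dag()].
#' @param categories Character vector of category term ids to test.
#' @param alpha Significance cutoff on the Bonferroni-corrected p-value.
#' @param direction `"greater"` (overrepresentation, default) or `"less"`.
#' @param use_part_of Also traverse part_of edges?
#' @return Tibble of class `enrichment_result`: `term`, `name`,
#'   `n_category`, `observed`, `expected`, `p_raw`, `p_bonferroni`,
#'   `significant`, sorted by `p_bonferroni` then term id; attribute
#'   `m_tests` records the Bonferroni factor.
#' @export
binomial_enrichment <- function(psg, reference, annotations, dag,
                                categories, alpha = 0.05,
                                direction = c("greater", "less"),
                                use_part_of = FALSE) {
  direction <- match.arg(direction)
  psg <- unique(psg)
  reference <- unique(reference)
  if (!all(psg %in% reference)) {
    abort("`psg` must be a subset of `reference`.")
  }
  hits <- gene_category_hits(annotations, dag, categories, use_part_of)
  hits <- hits[hits$gene %in% reference, , drop = FALSE]
  q <- length(psg) / length(reference)
  per_cat <- dplyr::group_by(hits, .data$category)
  per_cat <- dplyr::summarise(
    per_cat,
    n_category = dplyr::n_distinct(.data$gene),
    observed = dplyr::n_distinct(intersect(.data$gene, psg)),
    .groups = "drop")
  per_cat <- per_cat[per_cat$n_category >= 1L, , drop = FALSE]
  m <- nrow(per_cat)
  p_raw <- if (direction == "greater") {
    pbinom(per_cat$observed - 1L, per_cat$n_category, q,
           lower.tail = FALSE)
  } else {
    pbinom(per_cat$observed, per_cat$n_category, q)
  }
  out <- tibble::tibble(
    term = per_cat$category,
    name = unname(dag$names[per_cat$category]),
    n_category = per_cat$n_category,
    observed = per_cat$observed,
    expected = per_cat$n_category * q,
    p_raw = p_raw,
    p_bonferroni = pmin(1, m * p_raw),
    significant = pmin(1, m * p_raw) < alpha)
  out <- dplyr::arrange(out, .data$p_bonferroni, .data$term)
  attr(out, "m_tests") <- m
  class(out) <- c("enrichment_result", class(out))
  out
}
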