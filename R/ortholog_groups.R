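#' Ortholog group collections
#'
#' A collection of single-copy 1:1 ortholog groups is represented as a
#' tibble with one row per group: `group_id` and a `members` list-column,
#' each element a tibble with columns `species`, `protein`, `cds`. This is
#' the tabular analogue of OMA-style flat exports and is the unit the scan
#' pipeline iterates over.
#'
#' @param group_id Character vector of group identifiers.
#' @param members List of member tibbles (columns `species`, `protein`,
#'   `cds`), one per group; species unique within a group.
#' @return A tibble of class `ortholog_groups`.
#' @export
ortholog_groups <- function(group_id, members) {
  stopifnot(length(group_id) == length(members))
  for (k in seq_along(members)) {
    m <- members[[k]]
    if (!all(c("species", "protein", "cds") %in% names(m))) {
      abort("each members tibble needs columns species, protein, cds.")
    }
    if (anyDuplicated(m$species)) {
      abort(sprintf("duplicated species in group %s.", group_id[k]))
    }
  }
  out <- tibble::tibble(group_id = as.character(group_id),
                        members = members)
  class(out) <- c("ortholog_groups", class(out))
  out
}

group_species <- function(groups) {
  purrr::map(groups$members, "species")
}

#' Group filter specification
#'
#' Encodes the "non-exact search" constraints: a fixed set of species that
#' must be present in every kept group, a minimum total number of species
#' per group, and the wider taxon from which the unspecified members may
#' come (members outside it are dropped from kept groups).
#'
#' @param required_species Character vector (may be empty).
#' @param min_species Positive integer, at least `length(required_species)`.
#' @param allowed_taxon Character vector of permitted species; must contain
#'   all of `required_species`. `NULL` means no taxon restriction.
#' @return A list of class `group_filter_spec`.
#' @export
group_filter_spec <- function(required_species = character(),
                              min_species = 1L,
                              allowed_taxon = NULL) {
  min_species <- as.integer(min_species)
  if (min_species < 1L) abort("`min_species` must be >= 1.")
  if (min_species < length(required_species)) {
    abort("`min_species` cannot be below the number of required species.")
  }
  if (!is.null(allowed_taxon) &&
      !all(required_species %in% allowed_taxon)) {
    abort(paste0(
      "required species outside allowed_taxon: ",
      paste(setdiff(required_species, allowed_taxon), collapse = ", ")))
  }
  structure(list(required_species = unique(as.character(required_species)),
                 min_species = min_species,
                 allowed_taxon = if (is.null(allowed_taxon)) NULL
                                 else unique(as.character(allowed_taxon))),
            class = "group_filter_spec")
}

#' Filter ortholog groups by species constraints
#'
#' Keeps exactly the groups that (a) contain every required species and
#' (b) retain at least `min_species` members after restriction to the
#' allowed taxon. Members outside the allowed taxon are dropped from kept
#' groups (with a message per drop); input order is preserved.
#'
#' @param groups An [ortholog_groups()] collection.
#' @param spec A [group_filter_spec()].
#' @param quiet Suppress per-drop messages.
#' @return A filtered [ortholog_groups()] tibble.
#' @export
filter_groups <- function(groups, spec, quiet = FALSE) {
  stopifnot(inherits(spec, "group_filter_spec"))
  sp_list <- group_species(groups)
  keep <- logical(nrow(groups))
  members <- groups$members
  for (k in seq_len(nrow(groups))) {
    sp <- sp_list[[k]]
    in_taxon <- if (is.null(spec$allowed_taxon)) rep(TRUE, length(sp))
                else sp %in% spec$allowed_taxon
    if (!all(spec$required_species %in% sp)) next
    if (sum(in_taxon) < spec$min_species) next
    keep[k] <- TRUE
    if (!all(in_taxon)) {
      if (!quiet) {
        inform(sprintf("group %s: dropping %s (outside allowed taxon)",
                       groups$group_id[k],
                       paste(sp[!in_taxon], collapse = ", ")))
      }
      members[[k]] <- members[[k]][in_taxon, , drop = FALSE]
    }
  }
  out <- groups[keep, , drop = FALSE]
  out$members <- members[keep]
  out
}

#' Histogram of species counts per group
#'
#' The species-per-group distribution is the standard first summary of a
#' filtered ortholog collection (most mammalian groups in a genome-wide
#' scan carry 10 to ~33 species).
#'
#' @param groups An [ortholog_groups()] collection.
#' @return Tibble with columns `n_species`, `n_groups`, sorted by
#'   `n_species`; zero rows for an empty collection.
#' @export
group_size_histogram <- function(groups) {
  sizes <- lengths(group_species(groups))
  if (!length(sizes)) {
    return(tibble::tibble(n_species = integer(), n_groups = integer()))
  }
  tab <- table(sizes)
  tibble::tibble(n_species = as.integer(names(tab)),
                 n_groups = as.integer(tab))
}

#' Prune a master species topology to a subset of species
#'
#' Each ortholog group has its own species composition; its gene tree is
#' the induced subtree of the master topology on the group's species, with
#' unary internal nodes suppressed. When the master carries branch lengths,
#' path lengths between retained leaves are preserved.
#'
#' @param master An `ape::phylo` master topology (rooted; optional branch
#'   lengths).
#' @param species Character vector of leaves to retain (>= 2, >= 3 for any
#'   downstream model fitting).
#' @return An `ape::phylo` induced subtree.
#' @export
prune_master_tree <- function(master, species) {
  stopifnot(inherits(master, "phylo"))
  species <- unique(as.character(species))
  missing <- setdiff(species, master$tip.label)
  if (length(missing)) {
    abort(paste0("species not in master topology: ",
                 paste(missing, collapse = ", ")))
  }
  if (length(species) < 2L) abort("need at least 2 species to prune to.")
  if (setequal(species, master$tip.label)) {
    return(master)
  }
  ape::keep.tip(master, species)
}
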