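#' Read and write FASTA files
#'
#' Thin wrappers over Biostrings returning plain named character vectors,
#' the representation the rest of the package works with.
#'
#' @param file Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(file) {
  x <- Biostrings::readBStringSet(file)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, file, width = 70) {
  con <- file(file, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))),
               con)
  }
  invisible(file)
}

#' Assemble an ortholog-group collection from flat files
#'
#' Reads an OMA-style membership table (TSV with columns `group_id`,
#' `species`, `protein_id`, `cds_id`) and resolves sequences from protein
#' and CDS FASTA files by identifier. Group order follows first appearance
#' in the table.
#'
#' @param membership Path to the membership TSV.
#' @param protein_fasta,cds_fasta Paths to FASTA files keyed by
#'   `protein_id` / `cds_id`.
#' @return An [ortholog_groups()] collection.
#' @export
read_group_collection <- function(membership, protein_fasta, cds_fasta) {
  tab <- utils::read.delim(membership, stringsAsFactors = FALSE)
  need <- c("group_id", "species", "protein_id", "cds_id")
  if (!all(need %in% names(tab))) {
    abort(paste0("membership table needs columns: ",
                 paste(need, collapse = ", ")))
  }
  prot <- read_fasta(protein_fasta)
  cds <- read_fasta(cds_fasta)
  missing_p <- setdiff(tab$protein_id, names(prot))
  missing_c <- setdiff(tab$cds_id, names(cds))
  if (length(missing_p) || length(missing_c)) {
    abort(paste0("sequence ids missing from FASTA: ",
                 paste(head(c(missing_p, missing_c), 5), collapse = ", ")))
  }
  ids <- unique(tab$group_id)
  members <- lapply(ids, function(g) {
    sub <- tab[tab$group_id == g, , drop = FALSE]
    tibble::tibble(species = sub$species,
                   protein = unname(prot[sub$protein_id]),
                   cds = unname(cds[sub$cds_id]))
  })
  ortholog_groups(ids, members)
}

#' Write a group collection to flat files
#'
#' Inverse of [read_group_collection()]: writes the membership TSV and the
#' two FASTA files, with sequence ids `<group_id>|<species>`.
#'
#' @param groups An [ortholog_groups()] collection.
#' @param dir Output directory (created if needed).
#' @param prefix File name prefix.
#' @return Invisibly, the three file paths.
#' @export
write_group_collection <- function(groups, dir, prefix = "groups") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  long <- tidyr::unnest(groups, "members")
  ids <- paste0(long$group_id, "|", long$species)
  tab <- data.frame(group_id = long$group_id, species = long$species,
                    protein_id = ids, cds_id = ids)
  paths <- file.path(dir, paste0(prefix, c(".tsv", "_prot.fasta",
                                           "_cds.fasta")))
  utils::write.table(tab, paths[1], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_fasta(setNames(long$protein, ids), paths[2])
  write_fasta(setNames(long$cds, ids), paths[3])
  invisible(paths)
}

#' Write a codon alignment in sequential PHYLIP format
#'
#' @param caln A [codon_alignment()].
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_phylip <- function(caln, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf(" %d %d", length(caln),
                     attr(caln, "n_sites") * 3L), con)
  for (nm in names(caln)) {
    writeLines(sprintf("%-12s%s", nm, unclass(caln)[[nm]]), con)
  }
  invisible(file)
}

#' Write a scan result table as TSV
#'
#' @param table A `psg_scan` tibble (or any data frame).
#' @param file Output path.
#' @return Invisibly, the path.
#' @export
write_scan_table <- function(table, file) {
  utils::write.table(table, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
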