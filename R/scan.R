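#' Run the genome scan for positive selection
#'
#' Orchestrates the per-gene branch-site analysis: optionally filter the
#' group collection, prune the master topology to each group's species,
#' build the codon alignment by back-translation, estimate branch lengths
#' (M0 by default, shared between foregrounds), then for each foreground
#' species fit the null and alternative branch-site models with the
#' multi-start protocol and record the LRT. Per-gene failures are logged
#' and flagged, never abort the scan; results are deterministic given the
#' inputs.
#'
#' @param groups An [ortholog_groups()] collection (protein rows must be
#'   aligned within each group).
#' @param master An `ape::phylo` master topology covering all species.
#' @param foregrounds Character vector of one or two foreground species.
#' @param filter_spec Optional [group_filter_spec()]; applied first.
#' @param branch_lengths `"m0"` (estimate per gene under the one-ratio
#'   model, default) or `"master"` (use the pruned master's lengths).
#' @param alpha Significance cutoff for the LRT (default 0.05).
#' @param mixture Use the boundary mixture null distribution?
#' @param omega2_starts Starting omega values for the multi-start protocol.
#' @param min_leaves Minimum pruned-tree size to attempt a fit (default 3).
#' @param quiet Suppress per-gene progress messages.
#' @return A tibble of class `psg_scan`, one row per (gene, foreground):
#'   `group_id`, `foreground`, `n_species`, `n_sites`, `lnl_null`,
#'   `lnl_alt`, `lrt`, `p_value`, `significant`, `omega2_hat`, `status`
#'   (`"ok"`, `"skipped"`, or `"error"`), `note`, and an informational
#'   `p_fdr` column (Benjamini-Hochberg across the genes tested per
#'   foreground; not used for the `significant` flag).
#' @export
run_scan <- function(groups, master, foregrounds,
                     filter_spec = NULL, branch_lengths = c("m0", "master"),
                     alpha = 0.05, mixture = FALSE,
                     omega2_starts = c(0.5, 1, 2), min_leaves = 3L,
                     quiet = FALSE) {
  branch_lengths <- match.arg(branch_lengths)
  stopifnot(length(foregrounds) >= 1L, length(foregrounds) <= 2L)
  if (!is.null(filter_spec)) {
    groups <- filter_groups(groups, filter_spec, quiet = quiet)
  }
  rows <- list()
  emit <- function(gid, fg, n_sp, n_sites = NA_integer_,
                   lnl0 = NA_real_, lnl1 = NA_real_, lrt = NA_real_,
                   p = NA_real_, sig = NA, w2 = NA_real_,
                   status = "ok", note = "") {
    tibble::tibble(group_id = gid, foreground = fg,
                   n_species = n_sp, n_sites = n_sites,
                   lnl_null = lnl0, lnl_alt = lnl1, lrt = lrt,
                   p_value = p, significant = sig, omega2_hat = w2,
                   status = status, note = note)
  }
  for (k in seq_len(nrow(groups))) {
    gid <- groups$group_id[k]
    mem <- groups$members[[k]]
    n_sp <- nrow(mem)
    res_k <- tryCatch({
      tree <- prune_master_tree(master, mem$species)
      if (length(tree$tip.label) < min_leaves) {
        stop_skip <- TRUE
      } else {
        stop_skip <- FALSE
      }
      if (stop_skip) {
        purrr::map_dfr(foregrounds, function(fg) {
          emit(gid, fg, n_sp, status = "skipped",
               note = sprintf("pruned tree has %d < %d leaves",
                              length(tree$tip.label), min_leaves))
        })
      } else {
        caln <- back_translate(setNames(mem$protein, mem$species),
                               setNames(mem$cds, mem$species))
        pi <- estimate_codon_frequencies_f3x4(caln)
        if (branch_lengths == "m0") {
          tree_bl <- estimate_branch_lengths_m0(caln, tree, pi = pi)
        } else {
          if (is.null(tree$edge.length)) {
            abort("master topology carries no branch lengths.")
          }
          tree_bl <- tree
        }
        purrr::map_dfr(foregrounds, function(fg) {
          if (!fg %in% tree_bl$tip.label) {
            return(emit(gid, fg, n_sp, status = "skipped",
                        note = "foreground species absent from group"))
          }
          lt <- label_foreground(tree_bl, fg)
          ts <- branch_site_test(caln, lt, omega2_starts = omega2_starts,
                                 pi = pi, alpha = alpha, mixture = mixture)
          if (!quiet) {
            inform(sprintf(
              "%s [%s]: starts %d/%d, lnL %.3f / %.3f, p = %.3g",
              gid, fg, nrow(ts$null$starts), nrow(ts$alt$starts),
              ts$lrt$loglik_null, ts$lrt$loglik_alt, ts$lrt$p_value))
          }
          emit(gid, fg, n_sp, attr(caln, "n_sites"),
               ts$lrt$loglik_null, ts$lrt$loglik_alt, ts$lrt$statistic,
               ts$lrt$p_value, ts$lrt$significant, ts$alt$best$omega2)
        })
      }
    }, error = function(e) {
      purrr::map_dfr(foregrounds, function(fg) {
        emit(gid, fg, n_sp, status = "error",
             note = conditionMessage(e))
      })
    })
    rows[[k]] <- res_k
  }
  out <- dplyr::bind_rows(rows)
  # informational BH-FDR column per foreground; headline counts use the
  # raw per-gene p < alpha rule
  out$p_fdr <- NA_real_
  for (fg in unique(out$foreground)) {
    idx <- which(out$foreground == fg & out$status == "ok" &
                   !is.na(out$p_value))
    out$p_fdr[idx] <- stats::p.adjust(out$p_value[idx], method = "BH")
  }
  class(out) <- c("psg_scan", class(out))
  out
}

#' Genes under positive selection exclusively in one lineage
#'
#' With two foregrounds scanned symmetrically (e.g. dolphin and its sister
#' cow), the exclusive set for lineage `a` contains the genes significant
#' for `a` and not significant for `b`.
#'
#' @param table A `psg_scan` result containing both foregrounds.
#' @param foreground_a,foreground_b Foreground species names.
#' @return Character vector of group ids.
#' @export
exclusive_psg_set <- function(table, foreground_a, foreground_b) {
  present <- unique(table$foreground)
  missing <- setdiff(c(foreground_a, foreground_b), present)
  if (length(missing)) {
    abort(paste0("foreground(s) absent from scan table: ",
                 paste(missing, collapse = ", ")))
  }
  sig_of <- function(fg) {
    table$group_id[table$foreground == fg & table$status == "ok" &
                     !is.na(table$significant) & table$significant]
  }
  setdiff(sig_of(foreground_a), sig_of(foreground_b))
}

#' Summarize a positive-selection scan
#'
#' Per-foreground counts of tested and significant genes, with the
#' percentage (one decimal) that headlines genome scans, plus the
#' species-per-group histogram of the tested genes.
#'
#' @param table A `psg_scan` result (or any tibble with `foreground`,
#'   `status`, `significant`, and optionally `n_species` columns).
#' @return Tibble of class `scan_summary`: `foreground`, `n_tested`,
#'   `n_significant`, `percent_significant`; attribute
#'   `group_size_histogram` holds the histogram tibble.
#' @export
summary_report <- function(table) {
  if (!nrow(table)) abort("scan table is empty.")
  ok <- table[table$status == "ok" & !is.na(table$significant), ,
              drop = FALSE]
  out <- dplyr::summarise(
    dplyr::group_by(ok, .data$foreground),
    n_tested = dplyr::n(),
    n_significant = sum(.data$significant),
    .groups = "drop")
  out$percent_significant <- round(100 * out$n_significant / out$n_tested, 1)
  hist <- if ("n_species" %in% names(table)) {
    per_gene <- dplyr::distinct(ok, .data$group_id, .data$n_species)
    tab <- table(per_gene$n_species)
    tibble::tibble(n_species = as.integer(names(tab)),
                   n_groups = as.integer(tab))
  } else {
    tibble::tibble(n_species = integer(), n_groups = integer())
  }
  attr(out, "group_size_histogram") <- hist
  class(out) <- c("scan_summary", class(out))
  out
}
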