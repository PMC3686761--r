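#' Flag one branch of a tree as the foreground lineage
#'
#' Branch-site tests ask whether a designated (foreground) branch — here
#' typically the terminal branch of the focal species — harbours sites with
#' dN/dS > 1 while all other (background) branches do not. A labeled tree is
#' an `ape::phylo` plus the index of exactly one foreground edge.
#'
#' @param tree An `ape::phylo`.
#' @param foreground A tip label (flags the terminal branch above that tip)
#'   or an integer node number (flags the edge leading to that node).
#' @return An object of class `labeled_tree`: list with elements `tree` and
#'   `foreground_edge` (row index into `tree$edge`).
#' @export
label_foreground <- function(tree, foreground) {
  stopifnot(inherits(tree, "phylo"))
  if (is.character(foreground)) {
    hit <- match(foreground, tree$tip.label)
    if (is.na(hit)) {
      abort(sprintf("foreground species '%s' is not a tip of the tree.",
                    foreground))
    }
    node <- hit
  } else {
    node <- as.integer(foreground)
  }
  edge <- which(tree$edge[, 2] == node)
  if (length(edge) != 1L) {
    abort("foreground node has no unique parent edge (is it the root?).")
  }
  structure(list(tree = tree, foreground_edge = edge),
            class = "labeled_tree")
}

#' @export
print.labeled_tree <- function(x, ...) {
  child <- x$tree$edge[x$foreground_edge, 2]
  lab <- if (child <= length(x$tree$tip.label)) {
    x$tree$tip.label[child]
  } else {
    sprintf("internal node %d", child)
  }
  cat(sprintf("<labeled_tree> %d tips, foreground branch -> %s\n",
              length(x$tree$tip.label), lab))
  invisible(x)
}

#' Write a labeled tree in codeml-dialect newick
#'
#' The foreground branch is marked by a `#1` suffix on its child node's
#' label, the convention used by codeml tree files.
#'
#' @param x A [label_foreground()] tree.
#' @param file Optional path; when `NULL` the newick string is returned.
#' @return The newick string, invisibly when written to a file.
#' @export
write_labeled_tree <- function(x, file = NULL) {
  stopifnot(inherits(x, "labeled_tree"))
  tr <- x$tree
  child <- tr$edge[x$foreground_edge, 2]
  ntip <- length(tr$tip.label)
  if (child <= ntip) {
    tr$tip.label[child] <- paste0(tr$tip.label[child], "#1")
  } else {
    if (is.null(tr$node.label)) tr$node.label <- rep("", tr$Nnode)
    k <- child - ntip
    tr$node.label[k] <- paste0(tr$node.label[k], "#1")
  }
  s <- ape::write.tree(tr)
  if (is.null(file)) {
    return(s)
  }
  writeLines(s, file)
  invisible(s)
}

#' Read a codeml-dialect labeled newick tree
#'
#' @param text Newick string with one `#1`-suffixed node, or `file` a path.
#' @param file Optional path to read from instead of `text`.
#' @return A `labeled_tree`.
#' @export
read_labeled_tree <- function(text = NULL, file = NULL) {
  if (is.null(text)) text <- paste(readLines(file), collapse = "")
  tr <- ape::read.tree(text = text)
  ntip <- length(tr$tip.label)
  hits_tip <- grep("#1$", tr$tip.label)
  hits_node <- if (!is.null(tr$node.label)) grep("#1$", tr$node.label)
               else integer(0)
  if (length(hits_tip) + length(hits_node) != 1L) {
    abort("labeled newick must carry exactly one '#1' mark.")
  }
  if (length(hits_tip)) {
    tr$tip.label[hits_tip] <- sub("#1$", "", tr$tip.label[hits_tip])
    label_foreground(tr, hits_tip)
  } else {
    tr$node.label[hits_node] <- sub("#1$", "", tr$node.label[hits_node])
    label_foreground(tr, ntip + hits_node)
  }
}
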