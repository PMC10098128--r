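# Clock-likeness metrics: midpoint rooting and the variance of root-to-tip
# path lengths. A perfectly clocklike gene has variance 0.

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest tip-to-tip path, so the two
#' endpoints of the tree diameter are equidistant from the root.
#'
#' @param tree a `phylo` tree with branch lengths, >= 2 tips, at least one
#'   positive length.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have branch lengths")
  if (all(tree$edge.length == 0))
    stop("degenerate rooting: all branch lengths are zero")
  phangorn::midpoint(tree)
}

#' Root-to-tip distances and their variance
#'
#' @param tree a rooted `phylo` tree with branch lengths and >= 2 tips.
#' @return List of class `root_to_tip`: `distances` (named per-tip path
#'   lengths, substitutions/site), `variance` (sample variance, `n - 1`
#'   denominator) and `n_tips`.
#' @export
root_to_tip_variance <- function(tree) {
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("need >= 2 tips")
  depth <- ape::node.depth.edgelength(tree)
  d <- stats::setNames(depth[seq_len(ntip)], tree$tip.label)
  structure(list(distances = d, variance = stats::var(d), n_tips = ntip),
            class = "root_to_tip")
}

#' @export
print.root_to_tip <- function(x, ...) {
  cat("Root-to-tip report:", x$n_tips, "tips, variance",
      format(x$variance, digits = 6), "\n")
  invisible(x)
}

#' Prune a tree to a taxon subset
#'
#' Returns the induced subtree: degree-2 nodes created by the pruning are
#' suppressed with their branch lengths summed, so path lengths between
#' retained tips are unchanged. Node supports of the surviving nodes are
#' kept.
#'
#' @param tree a `phylo` tree.
#' @param taxa character vector, a subset of the tree's tips (>= 3).
#' @return The pruned `phylo` tree.
#' @export
prune_to_taxa <- function(tree, taxa) {
  unknown <- setdiff(taxa, tree$tip.label)
  if (length(unknown))
    stop("unknown taxon(s): ", paste(unknown, collapse = ", "))
  if (length(taxa) < 3L) stop("need >= 3 taxa after pruning")
  if (setequal(taxa, tree$tip.label)) return(tree)
  ape::keep.tip(tree, taxa)
}
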