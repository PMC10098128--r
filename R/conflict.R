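# Bipartition-based concordance/conflict mapping of gene trees onto a
# reference topology. For each internal reference edge and each gene tree,
# the reference split is restricted to the taxa the two trees share and then
# classified: concordant if the gene tree contains the restricted split,
# conflicting if the gene tree contains a split incompatible with it,
# uninformative otherwise (trivial after restriction, or unresolved).
# "Strong" means the supporting (or best-supported incompatible) gene-tree
# split has percent support at or above the threshold.

# two splits (as tip vectors) over a common taxon set are compatible iff one
# of the four intersections is empty
splits_compatible <- function(a, b, taxa) {
  ac <- setdiff(taxa, a)
  bc <- setdiff(taxa, b)
  !length(intersect(a, b)) || !length(intersect(a, bc)) ||
    !length(intersect(ac, b)) || !length(intersect(ac, bc))
}

#' Classify one reference split against one gene tree
#'
#' @param ref_split character vector: one side of the reference bipartition
#'   (over the reference taxon set).
#' @param ref_taxa full reference taxon set.
#' @param gene_tree a `phylo` gene tree (any rooting; may miss taxa).
#' @param support_threshold percent support defining "strong" (default 95).
#' @return List of class `edge_class`: `status`
#'   (`"concordant"`, `"conflict"`, `"uninformative"`), `strong` (logical)
#'   and `witness` (the most-supported incompatible gene split, conflicts
#'   only).
#' @export
classify_edge <- function(ref_split, ref_taxa, gene_tree,
                          support_threshold = 95) {
  shared <- intersect(ref_taxa, gene_tree$tip.label)
  res <- list(status = "uninformative", strong = FALSE, witness = NULL)
  class(res) <- "edge_class"
  side <- intersect(ref_split, shared)
  other <- setdiff(shared, side)
  if (length(side) < 2L || length(other) < 2L) return(res)  # trivial
  if (length(shared) < length(gene_tree$tip.label))
    gene_tree <- prune_to_taxa(gene_tree, shared)
  if (length(gene_tree$tip.label) < 4L) return(res)
  bip <- bipartition_set(gene_tree)
  key_side <- paste(sort(side), collapse = ",")
  key_other <- paste(sort(other), collapse = ",")
  hit <- match(key_side, names(bip$splits))
  if (is.na(hit)) hit <- match(key_other, names(bip$splits))
  if (!is.na(hit)) {
    sup <- bip$support[[hit]]
    res$status <- "concordant"
    res$strong <- !is.na(sup) && sup >= support_threshold
    return(res)
  }
  incomp <- Filter(function(key)
    !splits_compatible(bip$splits[[key]], side, shared),
    names(bip$splits))
  if (length(incomp)) {
    sup <- bip$support[incomp]
    sup[is.na(sup)] <- -Inf
    best <- incomp[which.max(sup)]
    res$status <- "conflict"
    res$strong <- is.finite(max(sup)) && max(sup) >= support_threshold
    res$witness <- bip$splits[[best]]
  }
  res
}

#' Concordance/conflict table of gene trees against a reference
#'
#' Applies [classify_edge()] to every (internal reference edge, gene tree)
#' pair and tallies counts; rows follow a preorder traversal of the
#' reference tree.
#'
#' @param reference_tree a `phylo` reference topology.
#' @param gene_trees list of `phylo` gene trees.
#' @param support_threshold percent support defining "strong" (default 95).
#' @return Data frame of class `conflict_table`: one row per internal
#'   reference edge with the clade (smaller side, sorted, comma-joined) and
#'   counts `n_concordant`, `n_concordant_strong`, `n_conflict`,
#'   `n_conflict_strong`, `n_uninformative`.
#' @export
conflict_table <- function(reference_tree, gene_trees, support_threshold = 95) {
  if (!length(gene_trees)) stop("need >= 1 gene tree")
  bip <- bipartition_set(reference_tree)
  ref_taxa <- reference_tree$tip.label
  # preorder: sort splits by node id in cladewise order
  ord <- order(bip$node)
  keys <- names(bip$splits)[ord]
  rows <- lapply(keys, function(key) {
    side <- bip$splits[[key]]
    cls <- lapply(gene_trees, function(gt)
      classify_edge(side, ref_taxa, gt, support_threshold))
    status <- vapply(cls, `[[`, "", "status")
    strong <- vapply(cls, `[[`, TRUE, "strong")
    small <- if (length(side) <= length(ref_taxa) / 2) side
      else sort(setdiff(ref_taxa, side))
    data.frame(
      edge = key, clade = paste(small, collapse = ","),
      n_concordant = sum(status == "concordant"),
      n_concordant_strong = sum(strong[status == "concordant"]),
      n_conflict = sum(status == "conflict"),
      n_conflict_strong = sum(strong[status == "conflict"]),
      n_uninformative = sum(status == "uninformative"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("conflict_table", "data.frame")
  out
}

#' Edges of one topology in strong conflict with another
#'
#' An edge of `treeA` is reported iff some bipartition of `treeB` with
#' support at or above the threshold is incompatible with it (after pruning
#' both trees to their shared taxa).
#'
#' @param treeA,treeB `phylo` trees sharing >= 4 taxa; `treeB` carries
#'   percent supports.
#' @param support_threshold percent (default 95).
#' @return Character vector of conflicting A-edge keys (canonical split
#'   keys; empty when the topologies agree at the threshold).
#' @export
topology_conflict_edges <- function(treeA, treeB, support_threshold = 95) {
  shared <- intersect(treeA$tip.label, treeB$tip.label)
  if (length(shared) < 4L) stop("need >= 4 shared taxa")
  if (length(shared) < length(treeA$tip.label))
    treeA <- prune_to_taxa(treeA, shared)
  if (length(shared) < length(treeB$tip.label))
    treeB <- prune_to_taxa(treeB, shared)
  bipA <- bipartition_set(treeA)
  bipB <- bipartition_set(treeB)
  strongB <- names(bipB$splits)[!is.na(bipB$support) &
                                  bipB$support >= support_threshold]
  out <- character(0)
  for (key in names(bipA$splits)) {
    clash <- any(vapply(strongB, function(kb)
      !splits_compatible(bipA$splits[[key]], bipB$splits[[kb]], shared),
      logical(1L)))
    if (clash) out <- c(out, key)
  }
  out
}
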