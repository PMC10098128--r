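# Bipartition machinery: every internal edge of an unrooted tree defines a
# split of the taxon set. Splits are stored canonically as the side NOT
# containing the reference taxon (the lexicographically smallest tip label),
# keyed by the sorted, comma-joined labels of that side.

#' Read a Newick tree
#'
#' Numeric internal-node labels are interpreted as percent supports on the
#' subtending edge. If every support lies in `[0, 1]` the file is assumed to
#' use fractions and supports are rescaled to percent with a warning.
#'
#' @param file path to a Newick file, or use `text`.
#' @param text optional Newick string.
#' @return A `phylo` tree.
#' @export
read_newick <- function(file, text = NULL) {
  tr <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(tr)) stop("could not parse Newick input")
  if (!is.null(tr$node.label)) {
    sup <- suppressWarnings(as.numeric(tr$node.label))
    ok <- !is.na(sup)
    if (any(ok) && all(sup[ok] <= 1) && any(sup[ok] > 0)) {
      warning("supports appear fractional (all <= 1); rescaling to percent")
      sup[ok] <- sup[ok] * 100
      tr$node.label[ok] <- format(sup[ok], trim = TRUE)
    }
    if (any(ok & (sup < 0 | sup > 100)))
      stop("supports outside [0, 100]")
  }
  tr$tip.label <- normalize_taxon_labels(tr$tip.label)
  if (anyDuplicated(tr$tip.label)) stop("duplicate tip labels")
  tr
}

#' Write a tree as Newick
#' @param tree a `phylo` tree.
#' @param file output path; omit to return the string.
#' @return The Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree, digits = 10)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

# per-edge percent supports: numeric for internal (child) edges carrying a
# numeric node label, NA otherwise
edge_supports <- function(tree) {
  ntip <- length(tree$tip.label)
  sup <- rep(NA_real_, nrow(tree$edge))
  if (!is.null(tree$node.label)) {
    lab <- suppressWarnings(as.numeric(tree$node.label))
    int <- tree$edge[, 2] > ntip
    sup[int] <- lab[tree$edge[int, 2] - ntip]
  }
  sup
}

#' Non-trivial bipartitions of a tree
#'
#' @param tree a `phylo` tree with >= 4 tips and unique tip labels.
#' @return List with `labels` (tip set), `splits` (named list: canonical key
#'   -> character vector of tips on the non-reference side), `node` (internal
#'   node id per split) and `support` (percent support per split, `NA` when
#'   absent).
#' @export
bipartition_set <- function(tree) {
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  ntip <- length(tree$tip.label)
  if (ntip < 4L) stop("need >= 4 tips for bipartitions")
  po <- stats::reorder(canon_tree(tree), "postorder")
  nnode <- ntip + tree$Nnode
  clade <- vector("list", nnode)
  clade[seq_len(ntip)] <- as.list(tree$tip.label)
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    clade[[p]] <- c(clade[[p]], clade[[ch]])
  }
  root <- po$edge[nrow(po$edge), 1]
  ref <- min(tree$tip.label)
  sup_all <- if (!is.null(tree$node.label))
    suppressWarnings(as.numeric(tree$node.label)) else rep(NA_real_, tree$Nnode)
  splits <- list(); node <- integer(0); support <- numeric(0)
  for (v in setdiff((ntip + 1L):nnode, root)) {
    side <- clade[[v]]
    if (length(side) < 2L || length(side) > ntip - 2L) next
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    side <- sort(side)
    key <- paste(side, collapse = ",")
    if (!is.null(splits[[key]])) next  # duplicated restriction (multifurcation artefacts)
    splits[[key]] <- side
    node[key] <- v
    support[key] <- sup_all[v - ntip]
  }
  list(labels = sort(tree$tip.label), splits = splits, node = node,
       support = support)
}

# write percent supports back onto internal node labels given a
# bipartition_set of the same tree
annotate_supports <- function(tree, bip, support_of) {
  ntip <- length(tree$tip.label)
  lab <- rep("", tree$Nnode)
  for (key in names(support_of)) {
    v <- bip$node[[key]]
    lab[v - ntip] <- format(support_of[[key]], trim = TRUE)
  }
  tree$node.label <- lab
  tree
}

#' Collapse poorly supported edges
#'
#' Contracts every internal edge whose percent support is below `threshold`
#' (edges without a support are treated as support 0), producing
#' multifurcations. Tip set unchanged; the contracted edges' branch lengths
#' are discarded.
#'
#' @param tree a `phylo` tree.
#' @param threshold percent in `[0, 100]`; 0 returns the tree unchanged.
#' @return The collapsed `phylo` tree.
#' @export
collapse_by_support <- function(tree, threshold) {
  stopifnot(threshold >= 0, threshold <= 101)
  if (threshold <= 0) return(tree)
  ntip <- length(tree$tip.label)
  sup <- edge_supports(tree)
  internal <- tree$edge[, 2] > ntip
  drop <- which(internal & (is.na(sup) | sup < threshold))
  if (!length(drop)) return(tree)
  nnode <- ntip + tree$Nnode
  merged_into <- seq_len(nnode)
  merged_into[tree$edge[drop, 2]] <- tree$edge[drop, 1]
  resolve <- function(v) { while (merged_into[v] != v) v <- merged_into[v]; v }
  keep <- setdiff(seq_len(nrow(tree$edge)), drop)
  old_int_kept <- sort(unique(c(vapply(tree$edge[keep, 1], resolve, 1L),
                                tree$edge[keep, 2][tree$edge[keep, 2] > ntip])))
  old_int_kept <- old_int_kept[old_int_kept > ntip]
  newid <- integer(nnode)
  newid[seq_len(ntip)] <- seq_len(ntip)
  newid[old_int_kept] <- ntip + seq_along(old_int_kept)
  edge <- cbind(newid[vapply(tree$edge[keep, 1], resolve, 1L)],
                newid[tree$edge[keep, 2]])
  out <- list(edge = edge,
              tip.label = tree$tip.label,
              Nnode = length(old_int_kept))
  if (!is.null(tree$edge.length)) out$edge.length <- tree$edge.length[keep]
  if (!is.null(tree$node.label))
    out$node.label <- tree$node.label[old_int_kept - ntip]
  class(out) <- "phylo"
  out <- stats::reorder(out, "cladewise")
  out
}

#' Unweighted Robinson-Foulds distance
#'
#' Symmetric difference of the two trees' non-trivial split sets. Trees with
#' unequal tip sets are pruned to the shared taxa first; with a support
#' threshold both trees are collapsed (missing supports count as 0) before
#' splits are compared.
#'
#' @param t1,t2 `phylo` trees sharing >= 4 tips.
#' @param support_threshold optional percent threshold.
#' @return Integer RF distance.
#' @export
rf_distance <- function(t1, t2, support_threshold = NULL) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4L) stop("need >= 4 shared tips")
  if (length(shared) < length(t1$tip.label)) t1 <- prune_to_taxa(t1, shared)
  if (length(shared) < length(t2$tip.label)) t2 <- prune_to_taxa(t2, shared)
  if (!is.null(support_threshold)) {
    t1 <- collapse_by_support(t1, support_threshold)
    t2 <- collapse_by_support(t2, support_threshold)
  }
  s1 <- names(bipartition_set(t1)$splits)
  s2 <- names(bipartition_set(t2)$splits)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Total tree length
#' @param tree a `phylo` tree with all branch lengths set.
#' @return Sum of all branch lengths (substitutions/site).
#' @export
tree_length <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree has missing branch lengths")
  sum(tree$edge.length)
}

#' Build an inverse-RF tree network
#'
#' Trees with RF distance 0 are merged into a single node carrying all their
#' labels; remaining pairs are connected by edges weighted `1 / RF`.
#'
#' @param trees named list of `phylo` trees on a common taxon set.
#' @param support_threshold optional percent threshold applied in every
#'   pairwise RF computation.
#' @return List of class `tree_network`: `nodes` (list of member label
#'   vectors), `edges` (data frame `from`, `to`, `rf`, `weight`) and
#'   `rf_matrix` (labelled all-by-all matrix).
#' @export
build_tree_network <- function(trees, support_threshold = NULL) {
  if (length(trees) < 2L) stop("need >= 2 trees")
  if (is.null(names(trees))) names(trees) <- paste0("tree", seq_along(trees))
  n <- length(trees)
  rf <- matrix(0L, n, n, dimnames = list(names(trees), names(trees)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    rf[i, j] <- rf[j, i] <- rf_distance(trees[[i]], trees[[j]],
                                        support_threshold)
  group <- integer(n)
  g <- 0L
  for (i in seq_len(n)) {
    if (group[i] == 0L) { g <- g + 1L; group[group == 0L & rf[i, ] == 0L] <- g
      group[i] <- g }
  }
  nodes <- split(names(trees), group)
  names(nodes) <- vapply(nodes, paste, "", collapse = "+")
  reps <- vapply(split(seq_len(n), group), `[`, 1L, 1L)
  edges <- NULL
  if (length(nodes) > 1L) {
    pairs <- utils::combn(length(nodes), 2L)
    edges <- data.frame(
      from = names(nodes)[pairs[1L, ]],
      to = names(nodes)[pairs[2L, ]],
      rf = rf[cbind(reps[pairs[1L, ]], reps[pairs[2L, ]])])
    edges$weight <- 1 / edges$rf
  } else {
    edges <- data.frame(from = character(0), to = character(0),
                        rf = integer(0), weight = numeric(0))
  }
  structure(list(nodes = nodes, edges = edges, rf_matrix = rf),
            class = "tree_network")
}

#' @export
print.tree_network <- function(x, ...) {
  cat("Tree network:", length(x$nodes), "topology node(s),",
      nrow(x$edges), "edge(s)\n")
  for (nm in names(x$nodes))
    cat("  [", nm, "]\n", sep = "")
  invisible(x)
}

#' Fruchterman-Reingold layout
#'
#' Classic force-directed placement: attractive force `d^2 / k` along edges,
#' repulsive force `k^2 / d` between all node pairs, with linear cooling; `k`
#' is the ideal edge length `sqrt(area / n)`. Deterministic given `seed`.
#'
#' @param network a `tree_network` (or any list with `nodes` and `edges`).
#' @param iterations force iterations (default 200).
#' @param seed RNG seed for the initial placement.
#' @param area layout area (default 1).
#' @return Data frame `node`, `x`, `y`.
#' @export
fr_layout <- function(network, iterations = 200L, seed = 1L, area = 1) {
  nodes <- names(network$nodes)
  n <- length(nodes)
  if (n == 1L) return(data.frame(node = nodes, x = 0, y = 0))
  k <- sqrt(area / n)
  pos <- with_seed(seed, matrix(stats::runif(2L * n, -0.5, 0.5), ncol = 2L))
  ei <- match(network$edges$from, nodes)
  ej <- match(network$edges$to, nodes)
  temp <- sqrt(area) / 10
  cool <- temp / (iterations + 1)
  for (it in seq_len(iterations)) {
    disp <- matrix(0, n, 2L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d <- pos[i, ] - pos[j, ]
      dist <- max(sqrt(sum(d^2)), 1e-9)
      f <- (k^2 / dist) * (d / dist)
      disp[i, ] <- disp[i, ] + f
      disp[j, ] <- disp[j, ] - f
    }
    for (e in seq_along(ei)) {
      d <- pos[ei[e], ] - pos[ej[e], ]
      dist <- max(sqrt(sum(d^2)), 1e-9)
      f <- (dist^2 / k) * (d / dist)
      disp[ei[e], ] <- disp[ei[e], ] - f
      disp[ej[e], ] <- disp[ej[e], ] + f
    }
    for (i in seq_len(n)) {
      dlen <- max(sqrt(sum(disp[i, ]^2)), 1e-9)
      pos[i, ] <- pos[i, ] + disp[i, ] / dlen * min(dlen, temp)
    }
    temp <- temp - cool
  }
  data.frame(node = nodes, x = pos[, 1L], y = pos[, 2L])
}
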