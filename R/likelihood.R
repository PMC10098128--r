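# Likelihood evaluation: site patterns are compressed once per
# (tree tips, alignment) pair and handed to the compiled pruning kernel.

# Compress alignment columns (restricted to the tree's tips, in tip order)
# into unique patterns with multiplicities.
pattern_table <- function(aln, tip_labels) {
  miss <- setdiff(tip_labels, rownames(aln))
  if (length(miss))
    stop("tip(s) missing from alignment: ", paste(miss, collapse = ", "))
  masks <- alignment_masks(aln)[tip_labels, , drop = FALSE]
  keys <- do.call(paste0, lapply(seq_len(nrow(masks)),
                                 function(i) sprintf("%x", masks[i, ])))
  first <- !duplicated(keys)
  idx <- match(keys, keys[first])
  w <- tabulate(idx, nbins = sum(first))
  list(codes = masks[, first, drop = FALSE], weights = w,
       pattern_of_site = idx)
}

# Precompute everything reusable across parameter values for one
# (tree topology, alignment) pair. Returns a closure evaluating lnL for
# given gtr_params and edge lengths (ordered as the postorder edge matrix).
lnl_machine <- function(tree, aln) {
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  tree <- stats::reorder(canon_tree(tree), "postorder")
  pt <- pattern_table(aln, tree$tip.label)
  ntip <- length(tree$tip.label)
  nnode_total <- ntip + tree$Nnode
  if (max(tree$edge) != nnode_total || length(tree$edge.length) != nrow(tree$edge))
    stop("malformed tree: node numbering or branch lengths inconsistent")
  edge <- tree$edge
  force(edge)
  list(
    tree = tree,
    edge = edge,
    nnode_total = nnode_total,
    nedge = nrow(edge),
    n_sites = ncol(aln),
    weights = pt$weights,
    loglik = function(params, elen = tree$edge.length) {
      if (any(elen < 0)) return(-Inf)
      e <- gtr_eigen(params)
      rates <- discrete_gamma_rates(params$alpha, params$ncat)
      ll <- .pruning_loglik(pt$codes, edge, elen, nnode_total,
                            e$vectors, e$inv, e$values, params$freqs,
                            rates, params$p_inv)
      sum(pt$weights * ll)
    },
    opt_branches = function(params, elen, lower = 1e-8, upper = 10,
                            nsweeps = 1L, iters = 24L) {
      e <- gtr_eigen(params)
      rates <- discrete_gamma_rates(params$alpha, params$ncat)
      .optimize_branches(list(pt$codes), edge, elen, nnode_total,
                         list(e$vectors), list(e$inv), list(e$values),
                         list(params$freqs), list(rates), params$p_inv,
                         list(pt$weights), 1, lower, upper,
                         as.integer(nsweeps), as.integer(iters))$elen
    },
    codes = pt$codes,
    pat_weights = pt$weights,
    site_loglik = function(params, elen = tree$edge.length) {
      e <- gtr_eigen(params)
      rates <- discrete_gamma_rates(params$alpha, params$ncat)
      ll <- .pruning_loglik(pt$codes, edge, elen, nnode_total,
                            e$vectors, e$inv, e$values, params$freqs,
                            rates, params$p_inv)
      ll[pt$pattern_of_site]
    })
}

#' Log-likelihood of an alignment on a tree under GTR+I+G
#'
#' Felsenstein pruning over compressed site patterns. Gap and ambiguity
#' characters are marginalised: a tip contributes partial likelihood 1 over
#' each state its IUPAC code allows, so an all-gap column contributes 0 to the
#' log-likelihood.
#'
#' @param tree a `phylo` tree with branch lengths; its tips must be a subset
#'   of the alignment's taxa.
#' @param aln a [nuc_alignment()].
#' @param params a [gtr_params()] object.
#' @return The log-likelihood (nats).
#' @export
tree_log_likelihood <- function(tree, aln, params) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("tree must have branch lengths set")
  lnl_machine(tree, aln)$loglik(params)
}

#' Per-partition log-likelihood contributions on a fixed tree
#'
#' With the topology and branch lengths held fixed, each partition's
#' substitution parameters are fitted independently and its log-likelihood
#' recorded; the contributions sum exactly to the total log-likelihood of the
#' per-partition model on that tree.
#'
#' @param tree fixed `phylo` tree with branch lengths.
#' @param aln a [nuc_alignment()].
#' @param scheme a [partition_scheme()].
#' @param model `"GTR+I+G"` (default) or `"GTR"` (no rate heterogeneity).
#' @param ... passed to [fit_gtr()].
#' @return Numeric vector of per-partition log-likelihoods (named), with
#'   attribute `total` (their sum).
#' @export
per_partition_contributions <- function(tree, aln, scheme,
                                        model = c("GTR+I+G", "GTR"), ...) {
  model <- match.arg(model)
  out <- vapply(seq_along(scheme$names), function(i) {
    sub <- partition_columns(aln, scheme, i, drop_empty = FALSE)
    fit <- fit_gtr(tree, sub, model = model,
                   free = c("exchangeabilities", "base_freqs",
                            if (model == "GTR+I+G") c("alpha", "p_inv")),
                   ...)
    fit$logLik
  }, numeric(1L))
  names(out) <- scheme$names
  attr(out, "total") <- sum(out)
  out
}
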