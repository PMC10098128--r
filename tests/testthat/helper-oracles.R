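# Independent oracles used across the suite. These deliberately avoid the
# package's pruning kernel: likelihoods are computed by exhaustive
# enumeration of internal-node states, bipartition work by direct set
# algebra.

.base_masks <- c(A = 1L, C = 2L, G = 4L, T = 8L, U = 8L, R = 5L, Y = 10L,
                 S = 6L, W = 9L, K = 12L, M = 3L, B = 14L, D = 13L,
                 H = 11L, V = 7L, N = 15L, `-` = 15L, `?` = 15L)

# exhaustive-enumeration log-likelihood (any tree small enough to enumerate
# internal states; mixture over gamma categories and invariant sites)
brute_lnl <- function(tree, aln, params) {
  tree <- reorder(tree, "postorder")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  masks <- matrix(.base_masks[unclass(aln)[tree$tip.label, , drop = FALSE]],
                  nrow = ntip)
  rates <- discrete_gamma_rates(params$alpha, params$ncat)
  root <- tree$edge[nrow(tree$edge), 1]
  internals <- (ntip + 1L):nn
  grid <- as.matrix(expand.grid(rep(list(1:4), length(internals))))
  nassign <- nrow(grid)
  total <- 0
  for (site in seq_len(ncol(masks))) {
    Lmix <- 0
    for (r in rates) {
      Ps <- lapply(seq_len(nrow(tree$edge)), function(e)
        transition_prob(params, tree$edge.length[e], r))
      pr <- params$freqs[grid[, match(root, internals)]]
      for (e in seq_len(nrow(tree$edge))) {
        pnode <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
        pstate <- grid[, match(pnode, internals)]
        if (ch <= ntip) {
          allowed <- which(bitwAnd(masks[ch, site], c(1L, 2L, 4L, 8L)) > 0)
          pr <- pr * rowSums(matrix(Ps[[e]][pstate, allowed],
                                    nrow = nassign))
        } else {
          pr <- pr * Ps[[e]][cbind(pstate, grid[, match(ch, internals)])]
        }
      }
      Lmix <- Lmix + sum(pr) / length(rates)
    }
    allowedall <- Reduce(bitwAnd, masks[, site])
    Linv <- sum(params$freqs[which(bitwAnd(allowedall, c(1L, 2L, 4L, 8L)) > 0)])
    total <- total + log(params$p_inv * Linv + (1 - params$p_inv) * Lmix)
  }
  total
}

# random GTR+I+G parameters (seeded by the caller)
random_params <- function(igg = TRUE) {
  f <- runif(4, 0.1, 0.4)
  gtr_params(rates = runif(6, 0.3, 3), freqs = f / sum(f),
             p_inv = if (igg) runif(1, 0, 0.3) else 0,
             alpha = if (igg) runif(1, 0.3, 2) else Inf)
}

# all unrooted binary topologies on the given tips (newick strings)
all_topologies <- function(tips) {
  if (length(tips) == 3L)
    return(paste0("(", tips[1], ",", tips[2], ",", tips[3], ");"))
  out <- character(0)
  base <- all_topologies(tips[-length(tips)])
  new <- tips[length(tips)]
  for (nwk in base) {
    tr <- ape::read.tree(text = nwk)
    for (e in seq_len(nrow(tr$edge))) {
      tr2 <- suppressWarnings(
        phytools::bind.tip(ape::compute.brlen(tr, 1), new,
                           where = tr$edge[e, 2], position = 0.5))
      out <- c(out, ape::write.tree(ape::unroot(tr2)))
    }
  }
  unique(out)
}

# compact alignment builder
aln_of <- function(...) nuc_alignment(c(...))
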