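# Detection of clade-restricted shifts in nucleotide composition on a fixed
# rooted topology. The model is deliberately explicit and simple: each tip's
# unambiguous base counts are multinomial draws from the base-frequency
# vector of the composition regime painted on its subtending edge. Regime 0
# (the root regime) covers the whole tree; each additional regime is
# introduced at one shift edge and inherited by the entire subtended clade
# (nearest-ancestor rule for nested shifts). Maximum-likelihood regime
# frequencies are pooled count proportions; regimes are added greedily while
# they improve an information criterion, honouring a minimum clade size.

# per-tip regime index (1 = root regime) given shift nodes in order
tip_regimes <- function(tree, shift_nodes) {
  ntip <- length(tree$tip.label)
  po <- stats::reorder(canon_tree(tree), "postorder")
  nnode <- ntip + tree$Nnode
  regime <- rep(1L, nnode)
  # preorder = reversed postorder edge list
  for (e in rev(seq_len(nrow(po$edge)))) {
    p <- po$edge[e, 1]; ch <- po$edge[e, 2]
    hit <- match(ch, shift_nodes)
    regime[ch] <- if (!is.na(hit)) hit + 1L else regime[p]
  }
  stats::setNames(regime[seq_len(ntip)], tree$tip.label)
}

# tips subtended by each node
clade_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  po <- stats::reorder(canon_tree(tree), "postorder")
  clade <- vector("list", ntip + tree$Nnode)
  clade[seq_len(ntip)] <- as.list(tree$tip.label)
  for (e in seq_len(nrow(po$edge)))
    clade[[po$edge[e, 1]]] <- c(clade[[po$edge[e, 1]]], clade[[po$edge[e, 2]]])
  clade
}

#' Composition log-likelihood of a regime painting
#'
#' @param tree rooted `phylo` tree.
#' @param shift_nodes integer vector of node ids whose subtending edges
#'   introduce new regimes (possibly empty).
#' @param counts per-tip base counts from [tip_base_counts()]; rows must
#'   cover all tips.
#' @param freqs optional list of per-regime frequency 4-vectors; when `NULL`
#'   (default) the maximum-likelihood pooled proportions are used. If any
#'   pooled cell is zero an additive smoothing of 0.5 per cell is applied to
#'   that regime.
#' @return List: `lnL`, `freqs` (per regime), `regimes` (per tip).
#' @export
regime_log_likelihood <- function(tree, shift_nodes, counts, freqs = NULL) {
  reg <- tip_regimes(tree, shift_nodes)
  miss <- setdiff(tree$tip.label, rownames(counts))
  if (length(miss)) stop("counts missing for tip(s): ",
                         paste(miss, collapse = ", "))
  counts <- counts[tree$tip.label, , drop = FALSE]
  nreg <- length(shift_nodes) + 1L
  if (is.null(freqs)) {
    freqs <- lapply(seq_len(nreg), function(r) {
      pooled <- colSums(counts[reg == r, , drop = FALSE])
      if (any(pooled == 0)) pooled <- pooled + 0.5
      pooled / sum(pooled)
    })
  }
  lnL <- sum(vapply(seq_len(nreg), function(r) {
    pooled <- colSums(counts[reg == r, , drop = FALSE])
    sum(pooled * log(freqs[[r]]))
  }, numeric(1L)))
  list(lnL = lnL, freqs = freqs, regimes = reg)
}

#' Candidate shift edges
#'
#' All internal edges whose subtended clade contains at least `min_clade`
#' tips; the root itself has no subtending edge and is excluded.
#'
#' @param tree rooted `phylo` tree.
#' @param min_clade minimum clade size (default 4).
#' @return Integer vector of candidate node ids (the child node of each
#'   candidate edge), with the subtended tip sets as attribute `clades`.
#' @export
candidate_shift_edges <- function(tree, min_clade = 4L) {
  ntip <- length(tree$tip.label)
  clade <- clade_tips(tree)
  root <- ntip + 1L
  cand <- setdiff((ntip + 1L):(ntip + tree$Nnode), root)
  cand <- cand[lengths(clade[cand]) >= min_clade]
  attr(cand, "clades") <- clade[cand]
  cand
}

#' Greedy search for compositional shifts
#'
#' Starts from the single-regime null; at each step the candidate edge whose
#' added regime most improves the criterion (k grows by 3 per regime, n is
#' the total unambiguous base count) is accepted; stops when no candidate
#' improves or `max_shifts` is reached. With fewer than `min_clade` tips the
#' result has zero shifts.
#'
#' @param tree rooted `phylo` tree, pruned to the gene's taxa.
#' @param aln the gene's [nuc_alignment()] (tips of `tree` must occur).
#' @param min_clade minimum clade size per shift (default 4).
#' @param criterion `"BIC"` (default), `"AICc"` or `"AIC"`.
#' @param max_shifts cap on added regimes (default 10).
#' @return Object of class `comp_shift`: `shift_nodes`, `shift_clades`
#'   (tip sets), `freqs`, `lnL`, `k`, `n`, `criterion`, `score`,
#'   `null_score`, `trace`, `tree`.
#' @export
greedy_shift_search <- function(tree, aln, min_clade = 4L,
                                criterion = c("BIC", "AICc", "AIC"),
                                max_shifts = 10L) {
  criterion <- match.arg(criterion)
  counts <- tip_base_counts(aln)
  n <- sum(counts)
  score_of <- function(lnL, nshift)
    information_criteria(lnL, 3L * (nshift + 1L), n)[[criterion]]
  null <- regime_log_likelihood(tree, integer(0), counts)
  cur_lnL <- null$lnL
  cur_score <- score_of(cur_lnL, 0L)
  null_score <- cur_score
  shifts <- integer(0)
  trace <- NULL
  cands <- if (length(tree$tip.label) >= min_clade)
    candidate_shift_edges(tree, min_clade) else integer(0)
  clades <- attr(cands, "clades")
  while (length(shifts) < max_shifts) {
    remaining <- setdiff(cands, shifts)
    if (!length(remaining)) break
    best <- NULL
    for (v in remaining) {
      fit <- regime_log_likelihood(tree, c(shifts, v), counts)
      sc <- score_of(fit$lnL, length(shifts) + 1L)
      if (is.null(best) || sc < best$score)
        best <- list(node = v, score = sc, lnL = fit$lnL)
    }
    if (best$score >= cur_score) break
    shifts <- c(shifts, best$node)
    trace <- rbind(trace, data.frame(step = length(shifts),
                                     node = best$node,
                                     score_before = cur_score,
                                     score_after = best$score))
    cur_score <- best$score
    cur_lnL <- best$lnL
  }
  final <- regime_log_likelihood(tree, shifts, counts)
  structure(list(shift_nodes = shifts,
                 shift_clades = lapply(match(shifts, cands),
                                       function(i) sort(clades[[i]])),
                 freqs = final$freqs, lnL = final$lnL,
                 k = 3L * (length(shifts) + 1L), n = n,
                 criterion = criterion, score = cur_score,
                 null_score = null_score, trace = trace, tree = tree),
            class = "comp_shift")
}

#' @export
print.comp_shift <- function(x, ...) {
  cat("Compositional shift search (", x$criterion, "): ",
      length(x$shift_nodes), " shift(s), lnL ", format(x$lnL, digits = 8),
      "\n", sep = "")
  for (cl in x$shift_clades)
    cat("  shift on clade {", paste(cl, collapse = ","), "}\n", sep = "")
  invisible(x)
}

#' Prevalence of shifts across genes for named clades
#'
#' A gene's shift matches a named clade when the shift edge subtends exactly
#' that clade restricted to the gene's taxa.
#'
#' @param per_gene_results named list of `comp_shift` objects.
#' @param named_clades named list of tip-label vectors.
#' @param tags optional character vector (same length as the results)
#'   grouping genes by dataset; fractions are then reported per tag as well.
#' @return Data frame: clade, (tag,) genes analysed, genes with a matching
#'   shift, fraction, and a `display` flag marking fractions >= 5%.
#' @export
shift_prevalence <- function(per_gene_results, named_clades, tags = NULL) {
  if (is.null(tags)) tags <- rep("all", length(per_gene_results))
  match_one <- function(res, clade) {
    restricted <- sort(intersect(clade, res$tree$tip.label))
    if (length(restricted) < 2L) return(FALSE)
    any(vapply(res$shift_clades, identical, TRUE, y = restricted))
  }
  rows <- list()
  for (cl_name in names(named_clades)) {
    for (tg in unique(tags)) {
      idx <- which(tags == tg)
      hit <- vapply(per_gene_results[idx], match_one, TRUE,
                    clade = named_clades[[cl_name]])
      rows[[length(rows) + 1L]] <- data.frame(
        clade = cl_name, tag = tg, n_genes = length(idx),
        n_with_shift = sum(hit), fraction = mean(hit),
        display = mean(hit) >= 0.05)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
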