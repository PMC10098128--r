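#' Neighbour-joining starting topology
#'
#' JC-corrected pairwise distances (pairwise deletion of gaps) fed to
#' neighbour joining; the result is unrooted with branch lengths floored at
#' 1e-8, suitable as a starting tree for likelihood fits.
#'
#' @param aln a [nuc_alignment()] with >= 4 taxa.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(aln) {
  d <- ape::dist.dna(ape::as.DNAbin(tolower(unclass(aln))), model = "JC69",
                     pairwise.deletion = TRUE)
  if (any(!is.finite(d))) d[!is.finite(d)] <- max(d[is.finite(d)], 0.1) * 2
  tr <- ape::unroot(ape::nj(d))
  tr$edge.length[tr$edge.length < 1e-8] <- 1e-8
  tr
}

# End-to-end orchestration: from tagged gene alignments to every result
# table of the analysis (combinability ranking, merged clusters, RF network,
# conflict tables, clock metrics, composition shifts). All stages call the
# exported module functions with the logged parameters, so each table is
# individually reproducible.

#' Run the full two-organelle analysis
#'
#' Stages, in order: per-tag and combined supermatrix concatenation; fits of
#' the four linking schemes on the combined data plus the summed
#' separate-trees candidate; combinability ranking; greedy partition merging
#' with a cluster-composition summary; all-by-all RF distances (with and
#' without the support threshold) with the inverse-RF network and layout;
#' reference-vs-reference conflict edges and per-gene conflict tables;
#' per-gene midpoint root-to-tip variance; per-gene compositional shift
#' search with clade prevalence.
#'
#' @param genes named list of [nuc_alignment()] gene alignments.
#' @param tags character vector (same names) assigning each gene to a
#'   dataset tag (two tags expected, e.g. `"plast"`, `"mito"`).
#' @param support_threshold percent support defining "strong" (default 95).
#' @param criterion information criterion for ranking and merging
#'   (default `"BIC"`).
#' @param min_clade minimum clade size for shift search (default 4).
#' @param seed RNG seed for every stochastic stage.
#' @param out_dir optional directory; when given, every table is written as
#'   tab-separated text plus a `run.log`.
#' @param gene_trees optional named list of per-gene trees (with supports);
#'   when absent, per-gene trees are inferred by NJ + NNI search and
#'   bootstrap supports are skipped in conflict counting.
#' @param fit_tol,fit_rounds optimiser settings forwarded to the fits.
#' @return List of class `study_result` with the per-stage outputs.
#' @export
run_study <- function(genes, tags, support_threshold = 95,
                      criterion = "BIC", min_clade = 4L, seed = 1L,
                      out_dir = NULL, gene_trees = NULL,
                      fit_tol = 1e-2, fit_rounds = 10L) {
  stopifnot(length(genes) >= 2L, !is.null(names(genes)))
  tags <- tags[names(genes)]
  log_lines <- c(sprintf("run_study seed=%d threshold=%s criterion=%s min_clade=%d",
                         seed, support_threshold, criterion, min_clade),
                 sprintf("genes=%d tags=%s", length(genes),
                         paste(sort(unique(tags)), collapse = ",")))
  stage <- function(msg) {
    log_lines <<- c(log_lines, paste0(format(Sys.time(), "%H:%M:%S "), msg))
  }

  stage("concatenate")
  combined <- concatenate_supermatrix(genes)
  per_tag <- lapply(split(names(genes), tags), function(gs)
    concatenate_supermatrix(genes[gs]))
  occupancy <- occupancy_report(genes)

  stage("starting topologies (NJ)")
  topo_combined <- nj_tree(combined$alignment)
  topo_tag <- lapply(per_tag, function(x) nj_tree(x$alignment))

  stage("linked fits on combined data")
  fits <- list()
  fits$unpartitioned <- fit_linked_scheme(combined$alignment, combined$scheme,
                                          "unpartitioned", topo_combined,
                                          tol = fit_tol, max_rounds = fit_rounds)
  fits$edge_equal <- fit_linked_scheme(combined$alignment, combined$scheme,
                                       "edge_equal", fits$unpartitioned$tree,
                                       init = fits$unpartitioned,
                                       tol = fit_tol, max_rounds = fit_rounds)
  fits$edge_proportional <- fit_linked_scheme(combined$alignment,
                                              combined$scheme,
                                              "edge_proportional",
                                              fits$unpartitioned$tree,
                                              init = fits$edge_equal,
                                              tol = fit_tol,
                                              max_rounds = fit_rounds)
  fits$edge_unlinked <- fit_linked_scheme(combined$alignment, combined$scheme,
                                          "edge_unlinked",
                                          fits$unpartitioned$tree,
                                          init = fits$edge_proportional,
                                          tol = fit_tol,
                                          max_rounds = fit_rounds)
  stage("separate-trees fits per tag")
  sep <- lapply(names(per_tag), function(tg)
    fit_linked_scheme(per_tag[[tg]]$alignment, per_tag[[tg]]$scheme,
                      "edge_proportional", topo_tag[[tg]],
                      tol = fit_tol, max_rounds = fit_rounds))
  names(sep) <- names(per_tag)
  fits$separate_trees <- combine_fits(sep, n_total = ncol(combined$alignment))

  stage("combinability ranking")
  ranking <- combinability_rank(fits)

  stage("greedy partition merging")
  merge_res <- greedy_merge_partitions(combined$alignment, combined$scheme,
                                       fits$unpartitioned$tree,
                                       criterion = criterion,
                                       tol = fit_tol, max_rounds = fit_rounds)
  mix <- cluster_mix_summary(merge_res$scheme, tags)

  stage("per-gene trees")
  if (is.null(gene_trees)) {
    gene_trees <- lapply(names(genes), function(g) {
      aln <- genes[[g]]
      if (nrow(aln) < 4L) return(NULL)
      nni_search(nj_tree(aln), aln, gtr_params(freqs = empirical_freqs(aln),
                                               alpha = 1))
    })
    names(gene_trees) <- names(genes)
    gene_trees <- Filter(Negate(is.null), gene_trees)
  }

  stage("RF network")
  ref_trees <- c(list(combined = fits$unpartitioned$tree),
                 lapply(sep, function(f) f$tree))
  rf_plain <- build_tree_network(ref_trees)
  layout <- fr_layout(rf_plain, seed = seed)

  stage("conflict analysis")
  ref <- sep[[1L]]$tree
  conflict <- conflict_table(ref, gene_trees, support_threshold)
  topo_conf <- if (length(sep) >= 2L)
    topology_conflict_edges(sep[[1L]]$tree, sep[[2L]]$tree,
                            support_threshold) else character(0)

  stage("root-to-tip variance")
  clock <- do.call(rbind, lapply(names(gene_trees), function(g) {
    tr <- gene_trees[[g]]
    rt <- root_to_tip_variance(midpoint_root(tr))
    data.frame(gene = g, tag = tags[[g]], n_tips = rt$n_tips,
               variance = rt$variance)
  }))

  stage("compositional shifts")
  shift_res <- lapply(names(genes), function(g) {
    tr <- gene_trees[[g]]
    if (is.null(tr)) return(NULL)
    greedy_shift_search(midpoint_root(tr), genes[[g]],
                        min_clade = min_clade, criterion = criterion)
  })
  names(shift_res) <- names(genes)
  shift_res <- Filter(Negate(is.null), shift_res)
  shift_tab <- do.call(rbind, lapply(names(shift_res), function(g)
    data.frame(gene = g, tag = tags[[g]],
               n_tips = length(shift_res[[g]]$tree$tip.label),
               n_shifts = length(shift_res[[g]]$shift_nodes),
               lnL = shift_res[[g]]$lnL, score = shift_res[[g]]$score)))

  out <- structure(list(
    combined = combined, per_tag = per_tag, occupancy = occupancy,
    fits = fits, ranking = ranking, merge = merge_res, cluster_mix = mix,
    gene_trees = gene_trees, network = rf_plain, layout = layout,
    conflict = conflict, topology_conflicts = topo_conf, clock = clock,
    shifts = shift_res, shift_table = shift_tab, log = log_lines,
    seed = seed), class = "study_result")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(df, f) utils::write.table(
      df, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(as.data.frame(ranking), "combinability.tsv")
    wt(occupancy, "occupancy.tsv")
    wt(mix, "cluster_mix.tsv")
    wt(conflict, "conflict_table.tsv")
    wt(clock, "root_to_tip.tsv")
    if (!is.null(shift_tab)) wt(shift_tab, "comp_shifts.tsv")
    wt(rf_plain$edges, "rf_network_edges.tsv")
    wt(layout, "rf_network_layout.tsv")
    utils::write.table(rf_plain$rf_matrix,
                       file.path(out_dir, "rf_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  out
}

#' @export
print.study_result <- function(x, ...) {
  cat("Study result:", length(x$gene_trees), "gene trees,",
      nrow(x$ranking), "combinability candidates\n")
  print(x$ranking)
  invisible(x)
}
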