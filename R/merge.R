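# Greedy agglomerative partition merging in the spirit of the
# PartitionFinder relaxation: starting from one cluster per gene, repeatedly
# apply the pair merge that most improves the information criterion of the
# whole edge-proportional model, until no merge improves. Branch lengths are
# re-optimised once per round on the current scheme, not per candidate pair.

#' Greedily merge partitions under an information criterion
#'
#' @param aln supermatrix [nuc_alignment()].
#' @param initial a [partition_scheme()] (typically one partition per gene).
#' @param topology fixed `phylo` topology.
#' @param linking linking scheme used for scoring (default
#'   `"edge_proportional"`).
#' @param criterion `"BIC"` (default), `"AICc"` or `"AIC"`.
#' @param tol,max_rounds,polish passed to [fit_linked_scheme()]; `polish`
#'   also controls the per-pair scoring fits.
#' @return List of class `partition_merge`: `scheme` (merged clusters, with
#'   attribute `members` listing the original partitions per cluster),
#'   `trace` (one row per accepted merge with the criterion delta), `fit`
#'   (final `linked_fit`) and `criterion`.
#' @details Ties between equally improving merges are broken by the
#'   lexicographically smallest pair of cluster names.
#' @export
greedy_merge_partitions <- function(aln, initial, topology,
                                    linking = "edge_proportional",
                                    criterion = c("BIC", "AICc", "AIC"),
                                    tol = 1e-3, max_rounds = 25L,
                                    polish = TRUE) {
  criterion <- match.arg(criterion)
  scheme <- initial
  members <- as.list(scheme$names)
  names(members) <- scheme$names
  trace <- NULL
  fit <- fit_linked_scheme(aln, scheme, linking, topology,
                           tol = tol, max_rounds = max_rounds,
                           polish = polish)
  crit_of <- function(f) information_criteria(f$logLik, f$k, f$n)[[criterion]]
  cur_crit <- crit_of(fit)
  step <- 0L
  while (length(scheme) > 1L) {
    p <- length(scheme)
    ntaxa <- fit$n_taxa
    elen <- fit$tree$edge.length
    mult <- fit$multipliers %||% rep(1, p)
    # score each candidate pair with branch lengths held at the round's fit
    pairs <- utils::combn(p, 2L)
    # deterministic tie-break: order pairs by cluster-name pair
    ord <- order(scheme$names[pairs[1L, ]], scheme$names[pairs[2L, ]])
    pairs <- pairs[, ord, drop = FALSE]
    best <- NULL
    for (q in seq_len(ncol(pairs))) {
      i <- pairs[1L, q]; j <- pairs[2L, q]
      merged_sites <- sort(c(scheme$sites[[i]], scheme$sites[[j]]))
      sub <- nuc_alignment(unclass(aln)[, merged_sites, drop = FALSE])
      machine <- lnl_machine(topology_with(fit$tree, elen), sub)
      start <- fit$params[[i]] %||% gtr_params(freqs = empirical_freqs(sub),
                                               alpha = 1, p_inv = 0.05)
      # fit substitution params and a cluster rate multiplier on fixed lengths
      m0 <- stats::weighted.mean(c(mult[i], mult[j]),
                                 c(length(scheme$sites[[i]]),
                                   length(scheme$sites[[j]])))
      lnL_m <- -Inf; par_m <- start; mult_m <- m0
      o <- .opt_subst(machine, par_m, elen * mult_m, polish = polish,
                      cycles = 1L)
      par_m <- o$params; lnL_m <- o$lnL
      om <- stats::optimize(function(lm)
        machine$loglik(par_m, elen * exp(lm)),
        interval = log(c(1e-3, 1e3)), maximum = TRUE, tol = 1e-5)
      if (om$objective >= lnL_m) { mult_m <- exp(om$maximum); lnL_m <- om$objective }
      new_lnL <- fit$logLik - fit$per_partition_lnL[i] -
        fit$per_partition_lnL[j] + lnL_m
      new_k <- count_free_parameters(linking, p - 1L, ntaxa)
      new_crit <- information_criteria(new_lnL, new_k, fit$n)[[criterion]]
      if (is.null(best) || new_crit < best$crit - 1e-9)
        best <- list(i = i, j = j, crit = new_crit, params = par_m,
                     mult = mult_m)
    }
    if (is.null(best) || best$crit >= cur_crit - 1e-9) break
    # apply the merge and refit the whole scheme (warm start)
    old_scheme <- scheme; old_members <- members
    i <- best$i; j <- best$j
    new_name <- paste(sort(c(scheme$names[i], scheme$names[j])), collapse = "+")
    new_members <- c(members, list(c(members[[i]], members[[j]])))
    new_members[c(i, j)] <- NULL
    names(new_members)[length(new_members)] <- new_name
    new_sites <- c(scheme$sites, list(sort(c(scheme$sites[[i]],
                                             scheme$sites[[j]]))))
    new_sites[c(i, j)] <- NULL
    names(new_sites) <- names(new_members)
    scheme <- partition_scheme(new_sites)
    members <- new_members
    init_params <- c(fit$params[-c(i, j)], list(best$params))
    init_mult <- c((fit$multipliers %||% rep(1, p))[-c(i, j)], best$mult)
    new_fit <- fit_linked_scheme(aln, scheme, linking, topology,
                                 init = list(tree = fit$tree,
                                             params = init_params,
                                             multipliers = unname(init_mult)),
                                 tol = tol, max_rounds = max_rounds,
                                 polish = polish)
    new_crit <- crit_of(new_fit)
    if (new_crit >= cur_crit) {
      # pair-level score promised an improvement the full refit did not
      # confirm; revert and stop
      scheme <- old_scheme
      members <- old_members
      break
    }
    step <- step + 1L
    trace <- rbind(trace, data.frame(
      step = step, merged = new_name,
      criterion_before = cur_crit, criterion_after = new_crit,
      delta = new_crit - cur_crit))
    fit <- new_fit
    cur_crit <- new_crit
  }
  structure(list(scheme = structure(scheme, members = members),
                 members = members, trace = trace, fit = fit,
                 criterion = criterion),
            class = "partition_merge")
}

topology_with <- function(tree, elen) {
  tree$edge.length <- elen
  tree
}

#' @export
print.partition_merge <- function(x, ...) {
  cat("Greedy partition merge (", x$criterion, "): ",
      length(x$scheme), " final cluster(s)\n", sep = "")
  if (!is.null(x$trace)) {
    cat("  merges:\n")
    for (r in seq_len(nrow(x$trace)))
      cat(sprintf("   %2d. %-30s delta %s = %.3f\n", x$trace$step[r],
                  x$trace$merged[r], x$criterion, x$trace$delta[r]))
  } else cat("  no merge improved the criterion\n")
  invisible(x)
}

#' Cluster composition by dataset of origin
#'
#' @param scheme a merged [partition_scheme()] (clusters), ideally carrying a
#'   `members` attribute from [greedy_merge_partitions()].
#' @param origin_labels named character vector mapping every original
#'   partition name to its dataset tag (e.g. `"plast"`, `"mito"`).
#' @return Data frame with one row per cluster: counts per tag, `mixed`
#'   flag and `singleton` flag; attribute `summary` gives totals of
#'   homogeneous vs mixed clusters and singleton counts per tag.
#' @export
cluster_mix_summary <- function(scheme, origin_labels) {
  members <- attr(scheme, "members") %||% as.list(scheme$names)
  tags <- sort(unique(origin_labels))
  rows <- lapply(seq_along(members), function(i) {
    mem <- members[[i]]
    if (any(!mem %in% names(origin_labels)))
      stop("unlabeled partition(s): ",
           paste(setdiff(mem, names(origin_labels)), collapse = ", "))
    cnt <- table(factor(origin_labels[mem], levels = tags))
    data.frame(cluster = scheme$names[i], n_genes = length(mem),
               t(as.integer(cnt)) |> as.data.frame() |>
                 stats::setNames(paste0("n_", tags)),
               mixed = sum(cnt > 0) > 1L,
               singleton = length(mem) == 1L)
  })
  out <- do.call(rbind, rows)
  singles <- out[out$singleton, paste0("n_", tags), drop = FALSE]
  attr(out, "summary") <- list(
    n_clusters = nrow(out),
    n_homogeneous = sum(!out$mixed),
    n_mixed = sum(out$mixed),
    singletons_per_tag = stats::setNames(colSums(singles), tags))
  out
}
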