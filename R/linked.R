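# Partition linking schemes and the information-criterion combinability
# test. Each partition carries its own GTR+I+G substitution parameters
# (10 free: 5 exchangeabilities, 3 frequencies, alpha, p_inv); the linking
# scheme decides how branch lengths are shared:
#   unpartitioned      one model, one set of branch lengths
#   edge_equal         shared branch lengths, per-partition substitution
#   edge_proportional  shared lengths up to per-partition rate multipliers
#                      (site-weighted mean 1, contributing p-1 parameters)
#   edge_unlinked      free branch lengths per partition, shared topology
#   separate_trees     fully independent trees per dataset; scored by summing
#                      lnL, n and k across the datasets

.linkings <- c("unpartitioned", "edge_equal", "edge_proportional",
               "edge_unlinked", "separate_trees")

#' Free-parameter count of a (linked) partitioned model
#'
#' Per partition the substitution model contributes
#' `per_partition_params` free parameters (default 10: 5 GTR
#' exchangeabilities, 3 base frequencies, invariant-sites proportion and
#' gamma shape); an unrooted tree on `T` taxa contributes `2T - 3` branch
#' lengths. Per entry: unpartitioned `10 + (2T-3)`; edge-equal
#' `10p + (2T-3)`; edge-proportional `10p + (2T-3) + (p-1)`; edge-unlinked
#' `10p + p(2T-3)`. Entries are summed, so a separate-trees candidate is a
#' list of entries.
#'
#' @param linking character vector of linking schemes (one per entry).
#' @param n_partitions integer vector `p` per entry (>= 1).
#' @param n_taxa integer vector `T` per entry (>= 4).
#' @param per_partition_params substitution parameters per partition
#'   (default 10).
#' @return Total free-parameter count `k` (integer).
#' @export
count_free_parameters <- function(linking, n_partitions, n_taxa,
                                  per_partition_params = 10L) {
  linking <- match.arg(linking, setdiff(.linkings, "separate_trees"),
                       several.ok = TRUE)
  per_partition_params <- as.integer(per_partition_params)
  m <- max(length(linking), length(n_partitions), length(n_taxa))
  linking <- rep_len(linking, m)
  p <- rep_len(as.integer(n_partitions), m)
  T <- rep_len(as.integer(n_taxa), m)
  if (any(p < 1L)) stop("n_partitions must be >= 1")
  if (any(T < 4L)) stop("n_taxa must be >= 4")
  br <- 2L * T - 3L
  k <- integer(m)
  for (i in seq_len(m)) {
    k[i] <- switch(linking[i],
      unpartitioned = per_partition_params + br[i],
      edge_equal = per_partition_params * p[i] + br[i],
      edge_proportional = per_partition_params * p[i] + br[i] + (p[i] - 1L),
      edge_unlinked = per_partition_params * p[i] + p[i] * br[i])
  }
  sum(k)
}

#' Information criteria from (lnL, k, n)
#'
#' `AIC = 2k - 2 lnL`; `AICc = AIC + 2k(k+1)/(n-k-1)`;
#' `BIC = k ln(n) - 2 lnL`. `n` is the total number of aligned sites.
#'
#' @param lnL maximised log-likelihood.
#' @param k free-parameter count.
#' @param n aligned-site count; must exceed `k + 1` for AICc.
#' @return Named numeric vector `c(AIC, AICc, BIC)`.
#' @export
information_criteria <- function(lnL, k, n) {
  lnL <- as.numeric(lnL); k <- as.numeric(k); n <- as.numeric(n)
  if (n <= k + 1) stop("AICc undefined: need n > k + 1")
  aic <- 2 * k - 2 * lnL
  c(AIC = aic,
    AICc = aic + 2 * k * (k + 1) / (n - k - 1),
    BIC = k * log(n) - 2 * lnL)
}

# ---- internal helpers for linked optimisation --------------------------

.subst_free <- c("exchangeabilities", "base_freqs", "alpha", "p_inv")

# optimise substitution parameters of one partition on fixed branch lengths
.opt_subst <- function(machine, params, elen, polish = TRUE, cycles = 2L) {
  obj <- function(q) machine$loglik(q, elen)
  cur <- obj(params)
  r <- .opt_cyclic(obj, params, cur, .subst_free)
  if (cycles > 1L)
    r <- .opt_cyclic(obj, r$params, r$lnL, .subst_free, width = 0.5)
  if (polish) r <- .opt_multivar(obj, r$params, r$lnL, .subst_free,
                                 maxit = 20L)
  r
}

#' Fit a partitioned model under a linking scheme
#'
#' @param aln supermatrix [nuc_alignment()].
#' @param scheme a [partition_scheme()] over the supermatrix columns.
#' @param linking one of `"unpartitioned"`, `"edge_equal"`,
#'   `"edge_proportional"`, `"edge_unlinked"`, `"separate_trees"`.
#' @param topology fixed `phylo` topology (ignored branch lengths). For
#'   `separate_trees`, a named list of topologies, one per dataset tag.
#' @param datasets for `separate_trees`: character vector mapping each
#'   partition to a dataset tag.
#' @param init optional warm start: a `linked_fit` of a nested scheme on the
#'   same data/topology.
#' @param tol log-likelihood convergence tolerance per round (default 1e-3).
#' @param max_rounds coordinate-ascent rounds (default 25).
#' @param mult_pin optionally pin all edge-proportional multipliers to 1
#'   (reduces the model to edge-equal; used for nesting checks).
#' @param polish as in [fit_gtr()]: final multivariate polish of the
#'   substitution parameters.
#' @return Object of class `linked_fit`: `logLik`, `k`, `n`, `linking`,
#'   `per_partition_lnL`, `tree` (or `trees`), `multipliers`, `params`
#'   (per-partition [gtr_params()]), `tree_length`, `n_taxa`.
#' @export
fit_linked_scheme <- function(aln, scheme, linking, topology,
                              datasets = NULL, init = NULL, tol = 1e-3,
                              max_rounds = 25L, mult_pin = FALSE,
                              polish = TRUE) {
  linking <- match.arg(linking, .linkings)
  if (linking == "separate_trees")
    return(.fit_separate_trees(aln, scheme, topology, datasets,
                               init = init, tol = tol,
                               max_rounds = max_rounds, polish = polish))
  ntaxa <- length(topology$tip.label)
  p <- length(scheme)

  if (linking == "unpartitioned") {
    p0 <- if (!is.null(init$params) && length(init$params))
      init$params[[1L]]
    fit <- fit_gtr(topology, aln, params0 = p0,
                   tol = tol, max_rounds = max_rounds, polish = polish)
    out <- list(logLik = fit$logLik,
                k = count_free_parameters("unpartitioned", 1L, ntaxa),
                n = ncol(aln), linking = linking,
                per_partition_lnL = stats::setNames(fit$logLik, "all"),
                tree = fit$tree, multipliers = NULL,
                params = list(all = fit$params),
                tree_length = tree_length(fit$tree), n_taxa = ntaxa,
                converged = fit$converged)
    class(out) <- "linked_fit"
    return(out)
  }

  if (linking == "edge_unlinked") {
    fits <- lapply(seq_len(p), function(i) {
      sub <- partition_columns(aln, scheme, i, drop_empty = FALSE)
      tr <- topology
      el <- if (!is.null(init$tree)) init$tree$edge.length
      tr$edge.length <- el %||% rep(0.1, nrow(tr$edge))
      if (!is.null(init$multipliers) && length(init$multipliers) == p)
        tr$edge.length <- tr$edge.length * init$multipliers[i]
      p0 <- if (!is.null(init$params) && length(init$params) >= i)
        init$params[[i]]
      fit_gtr(tr, sub, params0 = p0, tol = tol, max_rounds = max_rounds,
              polish = polish)
    })
    lnls <- stats::setNames(vapply(fits, `[[`, 0, "logLik"), scheme$names)
    out <- list(logLik = sum(lnls),
                k = count_free_parameters("edge_unlinked", p, ntaxa),
                n = ncol(aln), linking = linking,
                per_partition_lnL = lnls,
                trees = stats::setNames(lapply(fits, `[[`, "tree"), scheme$names),
                multipliers = NULL,
                params = stats::setNames(lapply(fits, `[[`, "params"), scheme$names),
                tree_length = vapply(fits, function(f) tree_length(f$tree), 0),
                n_taxa = ntaxa,
                converged = all(vapply(fits, `[[`, TRUE, "converged")))
    class(out) <- "linked_fit"
    return(out)
  }

  # edge_equal / edge_proportional: shared branch lengths
  subs <- lapply(seq_len(p), function(i)
    partition_columns(aln, scheme, i, drop_empty = FALSE))
  machines <- lapply(subs, function(s) lnl_machine(topology, s))
  nsites_p <- vapply(subs, ncol, integer(1L))
  nedge <- machines[[1L]]$nedge
  elen <- init$tree$edge.length %||% rep(0.1, nedge)
  if (length(elen) != nedge) elen <- rep(0.1, nedge)
  params <- lapply(seq_len(p), function(i) {
    ip <- init$params
    if (!is.null(ip)) {
      if (length(ip) >= i && inherits(ip[[i]], "gtr_params")) return(ip[[i]])
      if (length(ip) == 1L) return(ip[[1L]])
    }
    gtr_params(freqs = empirical_freqs(subs[[i]]), alpha = 1, p_inv = 0.05)
  })
  prop <- linking == "edge_proportional" && !mult_pin
  mult <- if (!is.null(init$multipliers) && length(init$multipliers) == p)
    init$multipliers else rep(1, p)
  if (!prop) mult <- rep(1, p)

  part_lnl <- function(i, el = elen, m = mult)
    machines[[i]]$loglik(params[[i]], el * m[i])
  lnls <- vapply(seq_len(p), part_lnl, 0)
  cur <- sum(lnls)
  converged <- FALSE
  rounds <- 0L
  do_polish <- FALSE
  while (rounds < max_rounds) {
    rounds <- rounds + 1L
    prev <- cur
    for (i in seq_len(p)) {
      obj <- local({ ii <- i; function(q) machines[[ii]]$loglik(q, elen * mult[ii]) })
      r <- .opt_cyclic(obj, params[[i]], lnls[i], .subst_free)
      if (do_polish) r <- .opt_multivar(obj, r$params, r$lnL, .subst_free)
      if (r$lnL > lnls[i]) { params[[i]] <- r$params; lnls[i] <- r$lnL }
    }
    if (prop && p > 1L) {
      for (i in seq_len(p)) {
        f <- function(lm) machines[[i]]$loglik(params[[i]], elen * exp(lm))
        o <- stats::optimize(f, interval = log(c(1e-3, 1e3)), maximum = TRUE,
                             tol = 1e-5)
        if (o$objective > lnls[i]) { mult[i] <- exp(o$maximum); lnls[i] <- o$objective }
      }
      # renormalise: site-weighted mean multiplier 1 (lnL-invariant)
      w <- sum(nsites_p * mult) / sum(nsites_p)
      mult <- mult / w
      elen <- elen * w
    }
    eigs <- lapply(params, gtr_eigen)
    elen2 <- .optimize_branches(
      lapply(machines, `[[`, "codes"), machines[[1L]]$edge, elen,
      machines[[1L]]$nnode_total,
      lapply(eigs, `[[`, "vectors"), lapply(eigs, `[[`, "inv"),
      lapply(eigs, `[[`, "values"), lapply(params, `[[`, "freqs"),
      lapply(params, function(q) discrete_gamma_rates(q$alpha, q$ncat)),
      vapply(params, `[[`, 0, "p_inv"),
      lapply(machines, `[[`, "pat_weights"), mult,
      1e-8, 10, 1L, 24L)$elen
    lnls2 <- vapply(seq_len(p), function(i) part_lnl(i, elen2), 0)
    if (sum(lnls2) > sum(lnls)) { elen <- elen2; lnls <- lnls2 }
    cur <- sum(lnls)
    gain <- cur - prev
    if (gain < tol && (do_polish || !polish)) { converged <- TRUE; break }
    if (polish && gain < 50 * tol) do_polish <- TRUE
  }
  tr <- machines[[1L]]$tree
  tr$edge.length <- elen
  k <- count_free_parameters(if (mult_pin) "edge_equal" else linking, p, ntaxa)
  out <- list(logLik = cur, k = k, n = ncol(aln), linking = linking,
              per_partition_lnL = stats::setNames(lnls, scheme$names),
              tree = tr,
              multipliers = if (prop) stats::setNames(mult, scheme$names),
              params = stats::setNames(params, scheme$names),
              tree_length = if (prop) sum(elen) * stats::weighted.mean(mult, nsites_p)
                else sum(elen),
              n_taxa = ntaxa, converged = converged)
  class(out) <- "linked_fit"
  out
}

.fit_separate_trees <- function(aln, scheme, topologies, datasets,
                                init = NULL, ...) {
  if (is.null(datasets) || length(datasets) != length(scheme))
    stop("separate_trees needs a dataset tag per partition")
  tags <- unique(datasets)
  fits <- lapply(tags, function(tg) {
    idx <- which(datasets == tg)
    genes <- lapply(idx, function(i)
      partition_columns(aln, scheme, i, drop_empty = TRUE))
    names(genes) <- scheme$names[idx]
    cat_sub <- concatenate_supermatrix(genes)
    topo <- if (inherits(topologies, "phylo")) topologies else topologies[[tg]]
    extra <- setdiff(topo$tip.label, rownames(cat_sub$alignment))
    if (length(extra))
      topo <- prune_to_taxa(topo, setdiff(topo$tip.label, extra))
    init_tg <- NULL
    if (!is.null(init)) {
      # warm start each dataset from the matching partitions of a nested
      # (typically edge-unlinked) fit on the same data
      nm <- scheme$names[idx]
      ip <- init$params[nm]
      it <- if (!is.null(init$trees) && !is.null(init$trees[[nm[1]]]))
        init$trees[[nm[1]]] else init$tree
      if (!is.null(it) &&
          length(it$edge.length) == nrow(topo$edge) &&
          setequal(it$tip.label, topo$tip.label))
        init_tg <- list(params = ip, tree = it)
      else if (!is.null(ip) && !anyNA(names(ip)))
        init_tg <- list(params = ip)
    }
    fit_linked_scheme(cat_sub$alignment, cat_sub$scheme,
                      "edge_proportional", topo, init = init_tg, ...)
  })
  names(fits) <- tags
  combine_fits(fits, n_total = ncol(aln))
}

#' Sum separately modelled fits into one combinability candidate
#'
#' Applies the separate-topology summation rule: the log-likelihoods, site
#' counts and free-parameter counts of the component fits are each summed
#' before information criteria are computed.
#'
#' @param fits named list of `linked_fit` objects whose data partition the
#'   full site set.
#' @param n_total expected total site count; the component `n` must sum to
#'   it exactly.
#' @return A `linked_fit` of linking `"separate_trees"`.
#' @export
combine_fits <- function(fits, n_total = NULL) {
  n <- sum(vapply(fits, function(f) as.numeric(f$n), 0))
  if (!is.null(n_total) && n != n_total)
    stop("consistency error: component site counts sum to ", n,
         ", expected ", n_total)
  out <- list(logLik = sum(vapply(fits, `[[`, 0, "logLik")),
              k = as.integer(sum(vapply(fits, function(f) as.numeric(f$k), 0))),
              n = as.integer(n), linking = "separate_trees",
              per_partition_lnL = unlist(lapply(fits, `[[`, "per_partition_lnL")),
              trees = lapply(fits, function(f) f$tree %||% f$trees),
              components = fits,
              multipliers = NULL, params = NULL,
              tree_length = vapply(fits, `[[`, 0, "tree_length"),
              n_taxa = vapply(fits, function(f) as.integer(f$n_taxa), 0L),
              converged = all(vapply(fits, `[[`, TRUE, "converged")))
  class(out) <- "linked_fit"
  out
}

#' @export
print.linked_fit <- function(x, ...) {
  cat("Partitioned fit (", x$linking, "): ",
      length(x$per_partition_lnL), " partition(s), n = ", x$n,
      ", k = ", x$k, "\n", sep = "")
  cat("  log-likelihood:", format(x$logLik, digits = 12), "\n")
  ic <- information_criteria(x$logLik, x$k, x$n)
  cat(sprintf("  AIC %.4f  AICc %.4f  BIC %.4f\n", ic[1], ic[2], ic[3]))
  invisible(x)
}

#' @export
logLik.linked_fit <- function(object, ...) {
  structure(object$logLik, df = object$k, nobs = object$n, class = "logLik")
}

#' Rank combinability candidates by information criteria
#'
#' Each candidate is a `linked_fit` (a list of them is first summed with
#' [combine_fits()]). The table reports `lnL`, `k`, `n` and the three
#' criteria; best-by-BIC and best-by-AICc are flagged. All candidates must
#' describe the same total site set.
#'
#' @param candidates named list of `linked_fit` objects or lists thereof.
#' @return Data frame of class `combinability_rank`, sorted by BIC.
#' @export
combinability_rank <- function(candidates) {
  if (is.null(names(candidates))) stop("candidates must be named")
  fits <- lapply(candidates, function(cd)
    if (inherits(cd, "linked_fit")) cd else combine_fits(cd))
  n <- vapply(fits, `[[`, 0, "n")
  if (length(unique(n)) != 1L)
    stop("consistency error: candidates disagree on n: ",
         paste(unique(n), collapse = ", "))
  tab <- data.frame(
    label = names(fits),
    linking = vapply(fits, `[[`, "", "linking"),
    lnL = vapply(fits, `[[`, 0, "logLik"),
    k = vapply(fits, `[[`, 0L, "k"),
    n = n, row.names = NULL)
  ic <- t(vapply(fits, function(f)
    information_criteria(f$logLik, f$k, f$n), numeric(3L)))
  tab <- cbind(tab, ic)
  tab <- tab[order(tab$BIC, tab$label), , drop = FALSE]
  tab$rank_BIC <- rank(tab$BIC, ties.method = "first")
  tab$rank_AICc <- rank(tab$AICc, ties.method = "first")
  tab$best_BIC <- tab$rank_BIC == 1L
  tab$best_AICc <- tab$rank_AICc == 1L
  rownames(tab) <- NULL
  class(tab) <- c("combinability_rank", "data.frame")
  tab
}

#' @export
print.combinability_rank <- function(x, ...) {
  cat("Combinability ranking (ascending BIC):\n")
  df <- as.data.frame(x)
  df$lnL <- sprintf("%.4f", df$lnL)
  df$AIC <- sprintf("%.4f", df$AIC)
  df$AICc <- sprintf("%.4f", df$AICc)
  df$BIC <- sprintf("%.4f", df$BIC)
  print(df[, c("label", "linking", "lnL", "k", "n", "AICc", "BIC",
               "best_AICc", "best_BIC")], row.names = FALSE)
  invisible(x)
}
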