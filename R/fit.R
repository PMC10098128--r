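# Maximum-likelihood fitting of the GTR+I+G model on a fixed topology by
# coordinate ascent: bounded 1-D (Brent) searches over individual branch
# lengths alternate with a bounded multivariate (L-BFGS-B) search over the
# substitution parameters until the log-likelihood gain per round drops
# below `tol`.

.free_all <- c("branch_lengths", "exchangeabilities", "base_freqs",
               "alpha", "p_inv")

empirical_freqs <- function(aln) {
  cnt <- colSums(tip_base_counts(aln)) + 1
  cnt / sum(cnt)
}

# pack/unpack substitution parameters to an unconstrained-ish bounded scale
.pack_params <- function(params, free) {
  par <- numeric(0); lo <- numeric(0); hi <- numeric(0); tag <- character(0)
  if ("exchangeabilities" %in% free) {
    par <- c(par, log(params$rates[1:5]))
    lo <- c(lo, rep(-9, 5)); hi <- c(hi, rep(9, 5))
    tag <- c(tag, rep("ex", 5))
  }
  if ("base_freqs" %in% free) {
    par <- c(par, log(params$freqs[1:3] / params$freqs[4]))
    lo <- c(lo, rep(-9, 3)); hi <- c(hi, rep(9, 3))
    tag <- c(tag, rep("fr", 3))
  }
  if ("alpha" %in% free) {
    par <- c(par, log(min(params$alpha, 90)))
    lo <- c(lo, log(0.02)); hi <- c(hi, log(99)); tag <- c(tag, "al")
  }
  if ("p_inv" %in% free) {
    par <- c(par, stats::qlogis(min(max(params$p_inv, 1e-4), 0.9)))
    lo <- c(lo, -9); hi <- c(hi, stats::qlogis(0.95)); tag <- c(tag, "pi")
  }
  list(par = par, lower = lo, upper = hi, tag = tag)
}

.unpack_params <- function(par, tag, template) {
  p <- template
  if (any(tag == "ex")) p$rates[1:5] <- exp(par[tag == "ex"])
  if (any(tag == "fr")) {
    w <- c(exp(par[tag == "fr"]), 1)
    p$freqs <- w / sum(w)
  }
  if (any(tag == "al")) p$alpha <- exp(par[tag == "al"])
  if (any(tag == "pi")) p$p_inv <- stats::plogis(par[tag == "pi"])
  p
}

# one pass of bounded 1-D (Brent) searches over each free substitution
# parameter on the transformed scale; cheap and monotone
.opt_cyclic <- function(loglik, params, cur, free, width = 1.5) {
  pk <- .pack_params(params, free)
  par <- pk$par
  for (d in seq_along(par)) {
    f <- function(x) {
      p2 <- par; p2[d] <- x
      v <- loglik(.unpack_params(p2, pk$tag, params))
      if (is.finite(v)) v else -1e12
    }
    o <- stats::optimize(f, c(max(pk$lower[d], par[d] - width),
                              min(pk$upper[d], par[d] + width)),
                         maximum = TRUE, tol = 1e-3)
    if (o$objective > cur) { par[d] <- o$maximum; cur <- o$objective }
  }
  list(params = .unpack_params(par, pk$tag, params), lnL = cur)
}

# bounded multivariate polish (L-BFGS-B on the transformed scale)
.opt_multivar <- function(loglik, params, cur, free, maxit = 40L) {
  pk <- .pack_params(params, free)
  fn <- function(x) {
    v <- loglik(.unpack_params(x, pk$tag, params))
    if (is.finite(v)) v else -1e12
  }
  opt <- stats::optim(pk$par, fn, method = "L-BFGS-B", lower = pk$lower,
                      upper = pk$upper,
                      control = list(fnscale = -1, maxit = maxit))
  if (opt$value > cur)
    list(params = .unpack_params(opt$par, pk$tag, params), lnL = opt$value)
  else list(params = params, lnL = cur)
}

#' Fit the GTR+I+G model on a tree by maximum likelihood
#'
#' @param tree a `phylo` tree; tips must occur in `aln`. Branch lengths, if
#'   absent, are initialised at 0.1.
#' @param aln a [nuc_alignment()].
#' @param params0 optional [gtr_params()] starting point; defaults to
#'   empirical base frequencies, equal exchangeabilities, `alpha = 1`,
#'   `p_inv = 0.05` (for GTR+I+G).
#' @param model `"GTR+I+G"` or `"GTR"` (no gamma, no invariant sites).
#' @param free subset of `c("branch_lengths", "exchangeabilities",
#'   "base_freqs", "alpha", "p_inv")` to optimise; the rest stay at their
#'   starting values.
#' @param tol stop when a full round improves the log-likelihood by less
#'   than this (default 1e-4 nats).
#' @param max_rounds maximum coordinate-ascent rounds (default 100).
#' @param branch_bounds bounds for each branch length
#'   (default `c(1e-8, 10)` substitutions/site).
#' @param ncat discrete gamma categories (default 4).
#' @param polish finish with a bounded multivariate (quasi-Newton) search
#'   once the cyclic updates stall (default TRUE). Disable for large-margin
#'   model comparisons where speed matters more than the last few
#'   hundredths of a nat.
#' @return An object of class `gtr_fit` with components `logLik`, `params`,
#'   `tree` (fitted branch lengths), `converged`, `iterations`, `n_sites`,
#'   `free` and `model`. Non-convergence is flagged, not an error.
#' @export
fit_gtr <- function(tree, aln, params0 = NULL, model = c("GTR+I+G", "GTR"),
                    free = .free_all, tol = 1e-4, max_rounds = 100L,
                    branch_bounds = c(1e-8, 10), ncat = 4L, polish = TRUE) {
  model <- match.arg(model)
  free <- match.arg(free, .free_all, several.ok = TRUE)
  if (model == "GTR") free <- setdiff(free, c("alpha", "p_inv"))
  if (is.null(params0)) {
    params0 <- gtr_params(freqs = empirical_freqs(aln),
                          alpha = if (model == "GTR+I+G") 1 else Inf,
                          p_inv = if (model == "GTR+I+G") 0.05 else 0,
                          ncat = ncat)
  }
  machine <- lnl_machine(tree, aln)
  elen <- machine$tree$edge.length
  params <- params0
  cur <- machine$loglik(params, elen)
  if (!is.finite(cur)) {  # recover from a degenerate start
    elen <- rep(0.1, machine$nedge)
    cur <- machine$loglik(params, elen)
  }
  sub_free <- setdiff(free, "branch_lengths")
  rounds <- 0L
  converged <- FALSE
  do_polish <- FALSE
  while (rounds < max_rounds) {
    rounds <- rounds + 1L
    prev <- cur
    if (length(sub_free)) {
      obj <- function(p2) machine$loglik(p2, elen)
      r <- .opt_cyclic(obj, params, cur, sub_free)
      params <- r$params; cur <- r$lnL
      if (do_polish) {
        r <- .opt_multivar(obj, params, cur, sub_free)
        params <- r$params; cur <- r$lnL
      }
    }
    if ("branch_lengths" %in% free) {
      elen2 <- machine$opt_branches(params, elen, branch_bounds[1L],
                                    branch_bounds[2L], nsweeps = 2L)
      v <- machine$loglik(params, elen2)
      if (v > cur) { elen <- elen2; cur <- v }
    }
    gain <- cur - prev
    if (gain < tol && (do_polish || !polish || !length(sub_free))) {
      converged <- TRUE; break
    }
    if (polish && gain < 50 * tol) do_polish <- TRUE  # close: full search

  }
  fitted_tree <- machine$tree
  fitted_tree$edge.length <- elen
  structure(list(logLik = cur, params = params, tree = fitted_tree,
                 converged = converged, iterations = rounds,
                 n_sites = machine$n_sites, free = free, model = model),
            class = "gtr_fit")
}

#' @export
print.gtr_fit <- function(x, ...) {
  cat(x$model, "fit:", length(x$tree$tip.label), "tips,", x$n_sites,
      "sites\n")
  cat("  log-likelihood:", format(x$logLik, digits = 10), "\n")
  cat("  converged:", x$converged, "after", x$iterations, "round(s)\n")
  print(x$params)
  invisible(x)
}

#' @export
logLik.gtr_fit <- function(object, ...) {
  k <- 0L
  if ("exchangeabilities" %in% object$free) k <- k + 5L
  if ("base_freqs" %in% object$free) k <- k + 3L
  if ("alpha" %in% object$free) k <- k + 1L
  if ("p_inv" %in% object$free) k <- k + 1L
  if ("branch_lengths" %in% object$free)
    k <- k + nrow(object$tree$edge)
  structure(object$logLik, df = k, nobs = object$n_sites, class = "logLik")
}

#' @export
coef.gtr_fit <- function(object, ...) {
  p <- object$params
  c(stats::setNames(p$rates, c("AC", "AG", "AT", "CG", "CT", "GT")),
    stats::setNames(p$freqs, c("piA", "piC", "piG", "piT")),
    alpha = p$alpha, p_inv = p$p_inv)
}

#' @export
simulate.gtr_fit <- function(object, nsim = 1, seed = NULL, n_sites = NULL, ...) {
  n_sites <- n_sites %||% object$n_sites
  seed <- seed %||% sample.int(2^30, 1L)
  out <- lapply(seq_len(nsim), function(i)
    simulate_alignment(object$tree, object$params, n_sites, seed = seed + i - 1L))
  if (nsim == 1L) out[[1L]] else out
}

#' Greedy nearest-neighbour-interchange topology search
#'
#' Hill-climbs over NNI rearrangements: every move that is accepted strictly
#' increases the branch-length-optimised log-likelihood (substitution
#' parameters held fixed); the search stops at a local optimum and returns
#' the start tree if no move improves.
#'
#' @param start_tree bifurcating `phylo` with >= 4 tips.
#' @param aln a [nuc_alignment()].
#' @param params a [gtr_params()] object (held fixed).
#' @param max_iter maximum accepted moves (default 50).
#' @param tol minimal improvement to accept a move (default 0.01 nats).
#' @param branch_rounds branch-length optimisation rounds used to score each
#'   neighbour (default 4; 1 gives a faster, rougher screen).
#' @return The locally optimal tree, with attributes `logLik` (final) and
#'   `lnL_trace` (strictly increasing log-likelihoods of accepted states).
#' @export
nni_search <- function(start_tree, aln, params, max_iter = 50L, tol = 1e-2,
                       branch_rounds = 4L) {
  # score under the supplied params (incl. any +I+G structure)
  score <- function(tr) {
    fit <- fit_gtr(tr, aln, params0 = params,
                   model = if (is.finite(params$alpha) || params$p_inv > 0)
                     "GTR+I+G" else "GTR",
                   free = "branch_lengths", tol = 1e-2,
                   max_rounds = branch_rounds)
    list(lnL = fit$logLik, tree = fit$tree)
  }
  cur <- score(start_tree)
  trace <- cur$lnL
  for (it in seq_len(max_iter)) {
    nbrs <- phangorn::nni(stats::reorder(canon_tree(cur$tree), "cladewise"))
    nbrs <- lapply(nbrs, canon_tree)
    best <- NULL
    for (nb in nbrs) {
      nb$edge.length <- rep(mean(cur$tree$edge.length), nrow(nb$edge))
      sc <- score(nb)
      if (is.null(best) || sc$lnL > best$lnL) best <- sc
    }
    if (is.null(best) || best$lnL <= cur$lnL + tol) break
    cur <- best
    trace <- c(trace, cur$lnL)
  }
  out <- cur$tree
  attr(out, "logLik") <- cur$lnL
  attr(out, "lnL_trace") <- trace
  out
}

#' Nonparametric bootstrap supports
#'
#' Sites are resampled with replacement; each replicate is refitted (branch
#' lengths, plus an NNI search when `search = "nni"`), and the support of an
#' internal edge is the percentage of replicate trees containing its
#' bipartition.
#'
#' @param aln a [nuc_alignment()].
#' @param params a [gtr_params()] object.
#' @param tree the tree whose edges are annotated.
#' @param n_reps number of replicates (>= 1).
#' @param seed RNG seed (mandatory; replicates are deterministic given it).
#' @param search `"nni"` (default) to re-search the topology per replicate,
#'   `"none"` to refit branch lengths only.
#' @return `tree` with percent supports in `$node.label` (internal nodes;
#'   root label empty).
#' @export
bootstrap_support <- function(aln, params, tree, n_reps = 100L, seed,
                              search = c("nni", "none")) {
  search <- match.arg(search)
  stopifnot(n_reps >= 1L)
  aln <- nuc_alignment(unclass(aln)[sort(rownames(aln)), , drop = FALSE])
  target <- bipartition_set(tree)
  counts <- stats::setNames(rep(0L, length(target$splits)),
                            names(target$splits))
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(ncol(aln), ncol(aln), replace = TRUE)
      rep_aln <- nuc_alignment(unclass(aln)[, cols, drop = FALSE])
      rep_tree <- if (search == "nni")
        nni_search(tree, rep_aln, params)
      else
        fit_gtr(tree, rep_aln, params0 = params, free = "branch_lengths",
                tol = 1e-2, max_rounds = 4L)$tree
      found <- bipartition_set(rep_tree)
      hit <- names(target$splits) %in% names(found$splits)
      counts[hit] <- counts[hit] + 1L
    }
  })
  support_of <- 100 * counts / n_reps
  annotate_supports(tree, target, support_of)
}
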