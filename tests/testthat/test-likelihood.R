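# Pruning likelihood against closed forms and exhaustive enumeration;
# invariances; fitting behaviour.

test_that("two-taxon JC likelihood matches the closed form", {
  tr <- read_newick(text = "(a:0.06,b:0.04);")
  p <- gtr_params()
  expect_equal(tree_log_likelihood(tr, aln_of(a = "A", b = "A"), p),
               log(0.25 * (0.25 + 0.75 * exp(-4 * 0.1 / 3))),
               tolerance = 1e-10)
  expect_equal(tree_log_likelihood(tr, aln_of(a = "A", b = "C"), p),
               log(0.25 * (0.25 - 0.25 * exp(-4 * 0.1 / 3))),
               tolerance = 1e-10)
})

test_that("pruning equals exhaustive enumeration on random instances", {
  set.seed(42)
  for (rep in 1:25) {
    nt <- sample(4:5, 1)
    tr <- sample_tree(nt, seed = rep, mean_branch_length = 0.3)
    pr <- random_params()
    aln <- simulate_alignment(tr, pr, sample(10:50, 1), seed = rep * 10)
    m <- unclass(aln)
    m[sample(length(m), round(0.08 * length(m)))] <- "-"
    m[sample(length(m), 3)] <- sample(c("N", "R", "Y", "W"), 3, TRUE)
    aln <- nuc_alignment(m)
    expect_equal(tree_log_likelihood(tr, aln, pr), brute_lnl(tr, aln, pr),
                 tolerance = 1e-9)
  }
})

test_that("all-gap columns contribute nothing", {
  tr <- sample_tree(5, seed = 3)
  pr <- random_params()
  aln <- simulate_alignment(tr, pr, 40, seed = 4)
  base <- tree_log_likelihood(tr, aln, pr)
  padded <- nuc_alignment(cbind(unclass(aln),
                                matrix("-", nrow(aln), 5)))
  expect_equal(tree_log_likelihood(tr, padded, pr), base, tolerance = 1e-10)
})

test_that("likelihood is invariant to rerooting and pattern compression", {
  set.seed(5)
  tr <- ape::unroot(sample_tree(6, seed = 6, mean_branch_length = 0.2))
  pr <- random_params()
  aln <- simulate_alignment(sample_tree(6, seed = 6, mean_branch_length = 0.2),
                            pr, 200, seed = 7)
  base <- tree_log_likelihood(tr, aln, pr)
  for (tip in c("t2", "t5")) {
    rr <- ape::root(tr, outgroup = tip, resolve.root = FALSE)
    expect_equal(tree_log_likelihood(rr, aln, pr), base, tolerance = 1e-8)
  }
  # permuting taxa (rows) must not matter
  perm <- nuc_alignment(unclass(aln)[sample(nrow(aln)), , drop = FALSE])
  expect_equal(tree_log_likelihood(tr, perm, pr), base, tolerance = 1e-10)
  # duplicating one column adds exactly that site's log-likelihood
  s1 <- nuc_alignment(unclass(aln)[, c(seq_len(200), 1), drop = FALSE])
  one <- nuc_alignment(unclass(aln)[, 1, drop = FALSE])
  expect_equal(tree_log_likelihood(tr, s1, pr),
               base + tree_log_likelihood(tr, one, pr), tolerance = 1e-8)
})

test_that("two-taxon branch MLE matches the closed-form JC distance", {
  tr <- read_newick(text = "(a:0.05,b:0.05);")
  aln <- simulate_alignment(tr, gtr_params(), 8000, seed = 7)
  phat <- mean(unclass(aln)[1, ] != unclass(aln)[2, ])
  fit <- fit_gtr(tr, aln, params0 = gtr_params(), model = "GTR",
                 free = "branch_lengths")
  expect_equal(sum(fit$tree$edge.length), -0.75 * log(1 - 4 * phat / 3),
               tolerance = 1e-4)
})

test_that("refitting at a returned optimum is idempotent", {
  tr <- sample_tree(6, seed = 11, mean_branch_length = 0.12)
  pr <- gtr_params(freqs = c(0.3, 0.2, 0.2, 0.3), alpha = 0.8)
  aln <- simulate_alignment(tr, pr, 800, seed = 12)
  fit <- fit_gtr(tr, aln, tol = 1e-3)
  refit <- fit_gtr(fit$tree, aln, params0 = fit$params, tol = 1e-3)
  expect_lt(abs(refit$logLik - fit$logLik), 0.05)
  expect_s3_class(fit, "gtr_fit")
  expect_true(is.finite(logLik(fit)))
  expect_named(coef(fit), c("AC", "AG", "AT", "CG", "CT", "GT",
                            "piA", "piC", "piG", "piT", "alpha", "p_inv"))
})

test_that("simulate-then-fit recovers generating parameters", {
  tr <- sample_tree(8, seed = 3, mean_branch_length = 0.15)
  truth <- gtr_params(rates = c(1.5, 4, 0.8, 1.2, 5, 1),
                      freqs = c(0.35, 0.15, 0.15, 0.35), alpha = 0.7)
  aln <- simulate_alignment(tr, truth, 10000, seed = 4)
  fit <- fit_gtr(tr, aln, tol = 0.01)
  expect_lt(abs(fit$params$alpha - 0.7), 0.15)
  expect_lt(max(abs(fit$params$freqs - truth$freqs)), 0.02)
  # simulate() method closes the loop on the fitted object
  sim <- simulate(fit, seed = 9, n_sites = 50)
  expect_s3_class(sim, "nuc_alignment")
  expect_equal(n_sites(sim), 50L)
})

test_that("per-partition contributions are exactly additive", {
  tr <- sample_tree(6, seed = 21, mean_branch_length = 0.1)
  pr <- gtr_params(freqs = c(0.3, 0.2, 0.2, 0.3), alpha = 1)
  g1 <- simulate_alignment(tr, pr, 300, seed = 22)
  g2 <- simulate_alignment(tr, gtr_params(freqs = c(0.2, 0.3, 0.3, 0.2),
                                          alpha = 1), 200, seed = 23)
  res <- concatenate_supermatrix(list(g1 = g1, g2 = g2))
  contrib <- per_partition_contributions(tr, res$alignment, res$scheme,
                                         tol = 0.01)
  expect_equal(length(contrib), 2L)
  expect_equal(sum(contrib), attr(contrib, "total"), tolerance = 1e-8)

  # single full-coverage partition equals the plain likelihood of its fit
  one <- partition_scheme(list(all = 1:500))
  c1 <- per_partition_contributions(tr, res$alignment, one, tol = 0.01)
  f1 <- fit_gtr(tr, res$alignment,
                free = c("exchangeabilities", "base_freqs", "alpha", "p_inv"),
                tol = 0.01)
  expect_equal(unname(c1[1]), f1$logLik, tolerance = 0.5)
  expect_equal(sum(c1), attr(c1, "total"))
})

test_that("nni search stays at the truth and recovers one-move scrambles", {
  pr <- gtr_params(freqs = c(0.3, 0.2, 0.2, 0.3), alpha = 1)
  hits <- 0L
  for (seed in 1:5) {
    truth <- ape::unroot(sample_tree(6, seed = seed,
                                     mean_branch_length = 0.15))
    aln <- simulate_alignment(truth, pr, 2500, seed = seed + 50)
    # start at the truth: no improving move expected
    stay <- nni_search(truth, aln, pr)
    expect_equal(rf_distance(stay, truth), 0L)
    trace <- attr(stay, "lnL_trace")
    expect_true(all(diff(trace) > 0) || length(trace) == 1L)
    # start one NNI away
    start <- perturb_nni(truth, 1, seed = seed + 100)
    found <- nni_search(start, aln, pr)
    if (rf_distance(found, truth) == 0L) hits <- hits + 1L
    expect_true(all(diff(attr(found, "lnL_trace")) > 0) ||
                  length(attr(found, "lnL_trace")) == 1L)
  }
  expect_gte(hits, 4L)
})

test_that("bootstrap supports behave at the edges and are order-invariant", {
  pr <- gtr_params(freqs = c(0.3, 0.2, 0.2, 0.3), alpha = 1)
  truth <- ape::unroot(sample_tree(6, seed = 31, mean_branch_length = 0.15))
  aln <- simulate_alignment(truth, pr, 1500, seed = 32)
  one <- bootstrap_support(aln, pr, truth, n_reps = 1, seed = 5,
                           search = "none")
  sup <- bipartition_set(one)$support
  expect_true(all(sup %in% c(0, 100)))

  b1 <- bootstrap_support(aln, pr, truth, n_reps = 5, seed = 9,
                          search = "none")
  perm <- nuc_alignment(unclass(aln)[rev(rownames(aln)), , drop = FALSE])
  b2 <- bootstrap_support(perm, pr, truth, n_reps = 5, seed = 9,
                          search = "none")
  expect_equal(bipartition_set(b1)$support, bipartition_set(b2)$support)
})
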