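# Parameter counting, information criteria, linking-scheme fits and the
# combinability ranking.

test_that("free-parameter counts follow the linking conventions", {
  # one gene, 4 taxa, unpartitioned: 10 substitution + 5 branch parameters
  expect_identical(count_free_parameters("unpartitioned", 1, 4), 15L)
  # edge-unlinked over p partitions equals p separate trees
  expect_identical(count_free_parameters("edge_unlinked", 2, 6),
                   2L * count_free_parameters("edge_proportional", 1, 6))
  expect_identical(count_free_parameters("edge_unlinked", 2, 6), 38L)
  # the two organellar gene sets on 226 taxa under edge-proportional
  expect_identical(count_free_parameters("edge_proportional", 79, 226), 1317L)
  expect_identical(count_free_parameters("edge_proportional", 39, 226), 877L)
  expect_identical(
    count_free_parameters(c("edge_proportional", "edge_proportional"),
                          c(79, 39), c(226, 226)), 2194L)
  # k strictly increases along the nesting order for p >= 2
  for (p in c(2, 5, 10)) for (T in c(4, 8, 20)) {
    ks <- vapply(c("unpartitioned", "edge_equal", "edge_proportional",
                   "edge_unlinked"),
                 function(l) count_free_parameters(l, p, T), 0L)
    expect_true(all(diff(ks) > 0))
  }
  expect_error(count_free_parameters("edge_equal", 0, 6), ">= 1")
  expect_error(count_free_parameters("edge_equal", 2, 3), ">= 4")
})

test_that("information criteria match direct arithmetic and edge cases", {
  ic <- information_criteria(-100, 2, 100)
  expect_equal(unname(ic["AIC"]), 204)
  expect_equal(unname(ic["AICc"]), 204 + 12 / 97)
  expect_equal(unname(ic["BIC"]), 2 * log(100) + 200)
  ic0 <- information_criteria(-100, 0, 50)
  expect_equal(unname(ic0["AIC"]), 200)
  expect_equal(unname(ic0["AICc"]), 200)
  expect_equal(unname(ic0["BIC"]), 200)
  expect_error(information_criteria(-10, 10, 11), "AICc")
  # AICc >= AIC always, converging as n grows
  expect_gte(information_criteria(-50, 5, 20)["AICc"],
             information_criteria(-50, 5, 20)["AIC"])
  expect_lt(information_criteria(-50, 5, 1e8)["AICc"] -
              information_criteria(-50, 5, 1e8)["AIC"], 1e-5)
})

test_that("proportional model with pinned multipliers reduces to edge-equal", {
  topo <- ape::unroot(sample_tree(6, seed = 41, mean_branch_length = 0.12))
  pr <- gtr_params(freqs = c(0.3, 0.2, 0.2, 0.3), alpha = 1)
  g1 <- simulate_alignment(topo, pr, 400, seed = 42)
  g2 <- simulate_alignment(topo, pr, 400, seed = 43)
  comb <- concatenate_supermatrix(list(g1 = g1, g2 = g2))
  f_eq <- fit_linked_scheme(comb$alignment, comb$scheme, "edge_equal", topo,
                            tol = 0.05, max_rounds = 10)
  f_pin <- fit_linked_scheme(comb$alignment, comb$scheme,
                             "edge_proportional", topo, mult_pin = TRUE,
                             init = f_eq, tol = 0.05, max_rounds = 10)
  expect_equal(f_pin$logLik, f_eq$logLik, tolerance = 0.01)
  expect_identical(f_pin$k, f_eq$k)
})

test_that("proportional multipliers satisfy the weighted-mean constraint and track rates", {
  topo <- ape::unroot(sample_tree(6, seed = 51, mean_branch_length = 0.1))
  pr <- gtr_params(freqs = c(0.3, 0.2, 0.2, 0.3), alpha = 1)
  fast <- topo; fast$edge.length <- topo$edge.length * 2
  g_slow <- simulate_alignment(topo, pr, 800, seed = 52)
  g_fast <- simulate_alignment(fast, pr, 400, seed = 53)
  comb <- concatenate_supermatrix(list(slow = g_slow, fast = g_fast))
  f <- fit_linked_scheme(comb$alignment, comb$scheme, "edge_proportional",
                         topo, tol = 0.05, max_rounds = 12)
  w <- c(800, 400)
  expect_equal(sum(w * f$multipliers) / sum(w), 1, tolerance = 1e-6)
  expect_gt(f$multipliers["fast"], f$multipliers["slow"])
  expect_equal(unname(f$multipliers["fast"] / f$multipliers["slow"]), 2,
               tolerance = 0.35)
})

test_that("maximised lnL is monotone along the nesting order", {
  pr <- gtr_params(freqs = c(0.3, 0.2, 0.2, 0.3), alpha = 1)
  topo <- ape::unroot(sample_tree(6, seed = 61, mean_branch_length = 0.12))
  g1 <- simulate_alignment(topo, pr, 500, seed = 62)
  tr2 <- topo; tr2$edge.length <- topo$edge.length * 1.7
  g2 <- simulate_alignment(tr2, pr, 500, seed = 63)
  comb <- concatenate_supermatrix(list(g1 = g1, g2 = g2))
  tol <- 0.1; mr <- 8
  f_un <- fit_linked_scheme(comb$alignment, comb$scheme, "unpartitioned",
                            topo, tol = tol, max_rounds = mr, polish = FALSE)
  f_eq <- fit_linked_scheme(comb$alignment, comb$scheme, "edge_equal",
                            f_un$tree, init = f_un, tol = tol,
                            max_rounds = mr, polish = FALSE)
  f_pr <- fit_linked_scheme(comb$alignment, comb$scheme, "edge_proportional",
                            f_un$tree, init = f_eq, tol = tol,
                            max_rounds = mr, polish = FALSE)
  f_ul <- fit_linked_scheme(comb$alignment, comb$scheme, "edge_unlinked",
                            f_un$tree, init = f_pr, tol = tol,
                            max_rounds = mr, polish = FALSE)
  f_sep <- fit_linked_scheme(comb$alignment, comb$scheme, "separate_trees",
                             list(g1 = topo, g2 = topo),
                             datasets = c("g1", "g2"), init = f_ul,
                             tol = tol, max_rounds = mr, polish = FALSE)
  lnls <- c(f_un$logLik, f_eq$logLik, f_pr$logLik, f_ul$logLik, f_sep$logLik)
  expect_true(all(diff(lnls) > -1e-3))
  expect_identical(f_ul$k, f_sep$k)  # unlinked prices like two free trees
})

test_that("combine_fits applies the summation rule and checks n", {
  mk <- function(lnL, k, n) structure(
    list(logLik = lnL, k = as.integer(k), n = as.integer(n),
         linking = "edge_proportional", per_partition_lnL = lnL,
         tree = NULL, tree_length = 1, n_taxa = 8, converged = TRUE),
    class = "linked_fit")
  cmb <- combine_fits(list(A = mk(-2000, 20, 1000), B = mk(-1000, 15, 500)),
                      n_total = 1500)
  expect_equal(cmb$logLik, -3000)
  expect_identical(cmb$k, 35L)
  expect_identical(cmb$n, 1500L)
  expect_error(combine_fits(list(A = mk(-1, 2, 10), B = mk(-1, 2, 10)),
                            n_total = 30), "consistency")
  # the study's printed summation: components reproducing lnL/n/k totals
  tot <- combine_fits(list(P = mk(-2322541.5178, 1317, 103806),
                           M = mk(-711593.1764, 877, 58295)))
  expect_equal(tot$n, 162101L)
  expect_identical(tot$k, 2194L)
  ic <- information_criteria(-3034134.6942, tot$k, tot$n)
  expect_equal(unname(ic["BIC"]), 6094588.557, tolerance = 0.01)
})

test_that("ranking flags the best candidates and ignores input order", {
  mk <- function(lnL, k) structure(
    list(logLik = lnL, k = as.integer(k), n = 10000L, linking = "edge_equal",
         per_partition_lnL = lnL, tree = NULL, tree_length = 1,
         n_taxa = 8, converged = TRUE), class = "linked_fit")
  cands <- list(a = mk(-5000, 20), b = mk(-4950, 40), c = mk(-4995, 25))
  rk1 <- combinability_rank(cands)
  rk2 <- combinability_rank(rev(cands))
  expect_equal(rk1$label, rk2$label)
  expect_equal(rk1$BIC, rk2$BIC)
  best <- rk1$label[rk1$best_BIC]
  oracle <- names(cands)[which.min(vapply(cands, function(f)
    information_criteria(f$logLik, f$k, f$n)["BIC"], 0))]
  expect_equal(best, oracle)
  single <- combinability_rank(list(only = mk(-10, 5)))
  expect_true(single$best_BIC[1] && single$best_AICc[1])
})
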