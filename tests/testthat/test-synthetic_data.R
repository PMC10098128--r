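# Generators: determinism, topology uniformity, simulation moments and the
# two-organelle study structure.

test_that("sampled trees are seeded, sized and near-uniform over shapes", {
  t1 <- sample_tree(6, seed = 5)
  t2 <- sample_tree(6, seed = 5)
  expect_equal(write_newick(t1), write_newick(t2))
  expect_equal(nrow(ape::unroot(t1)$edge), 2 * 6 - 3)
  # 4 taxa: the three unrooted topologies appear in ~equal proportion
  keys <- vapply(1:3000, function(s) {
    tr <- ape::unroot(sample_tree(4, seed = 10000 + s))
    names(bipartition_set(tr)$splits)[1]
  }, "")
  freq <- table(keys) / 3000
  expect_length(freq, 3L)
  expect_true(all(abs(freq - 1 / 3) < 0.03))
})

test_that("simulated alignments match closed-form expectations", {
  # near-zero branches: identical sequences
  tr <- read_newick(text = "(a:1e-9,b:1e-9,(c:1e-9,d:1e-9):1e-9);")
  aln <- simulate_alignment(tr, gtr_params(), 200, seed = 7)
  expect_true(all(apply(unclass(aln), 2, function(col)
    length(unique(col)) == 1L)))
  # JC expected mismatch fraction at t = 0.3
  tr2 <- read_newick(text = "(a:0.15,b:0.15);")
  aln2 <- simulate_alignment(tr2, gtr_params(), 10000, seed = 8)
  phat <- mean(unclass(aln2)[1, ] != unclass(aln2)[2, ])
  p_exp <- 0.75 * (1 - exp(-4 * 0.3 / 3))
  expect_lt(abs(phat - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / 10000))
  # stationarity: empirical base frequencies near pi
  pr <- gtr_params(freqs = c(0.4, 0.1, 0.2, 0.3), alpha = 1)
  tr3 <- sample_tree(10, seed = 9, mean_branch_length = 0.3)
  aln3 <- simulate_alignment(tr3, pr, 4000, seed = 10)
  emp <- colSums(tip_base_counts(aln3)) / sum(tip_base_counts(aln3))
  expect_true(all(abs(emp - pr$freqs) < 0.03))
  # determinism
  expect_identical(unclass(simulate_alignment(tr3, pr, 100, seed = 11)),
                   unclass(simulate_alignment(tr3, pr, 100, seed = 11)))
})

test_that("shift simulation reduces to the plain path without shifts", {
  tr <- sample_tree(8, seed = 12, mean_branch_length = 0.1)
  pr <- gtr_params(freqs = c(0.3, 0.2, 0.2, 0.3), alpha = 1)
  a <- simulate_alignment(tr, pr, 150, seed = 13)
  b <- simulate_composition_shift_alignment(tr, list(), pr, 150, seed = 13)
  expect_identical(unclass(a), unclass(b))
  expect_error(simulate_composition_shift_alignment(
    tr, list(list(node = 10L, freqs = c(1, 2, -1, 0))), pr, 50, seed = 1),
    "invalid")
})

test_that("a strong planted shift moves the clade's composition by design", {
  tr <- sample_tree(12, seed = 14, mean_branch_length = 0.15)
  cand <- candidate_shift_edges(tr, 4)
  pick <- cand[1]
  clade <- phylocomb:::clade_tips(tr)[[pick]]
  gc_rich <- c(0.1, 0.4, 0.4, 0.1)
  aln <- simulate_composition_shift_alignment(
    tr, list(list(node = pick, freqs = gc_rich)),
    gtr_params(freqs = c(0.35, 0.15, 0.15, 0.35), alpha = 1), 3000,
    seed = 15)
  cnt <- tip_base_counts(aln)
  gc <- (cnt[, "C"] + cnt[, "G"]) / attr(cnt, "total")
  expect_gt(mean(gc[clade]) - mean(gc[setdiff(rownames(cnt), clade)]), 0.2)
})

test_that("NNI perturbation respects the RF bound and seeds", {
  tr <- ape::unroot(sample_tree(8, seed = 16))
  expect_identical(write_newick(perturb_nni(tr, 0, seed = 1)),
                   write_newick(tr))
  for (seed in 1:6) {
    one <- perturb_nni(tr, 1, seed = seed)
    expect_equal(rf_distance(tr, one), 2L)
    many <- perturb_nni(tr, 3, seed = seed)
    expect_lte(rf_distance(tr, many), 6L)
  }
})

test_that("the organelle study emulates the two-compartment design", {
  cfg <- study_config(n_taxa = 12, n_plast = 4, n_mito = 3,
                      gene_sites = 300, occupancy = 0.85, seed = 17)
  st <- simulate_organelle_study(cfg)
  expect_length(st$genes, 7L)
  expect_equal(as.integer(table(st$tags)[c("plast", "mito")]), c(4L, 3L))
  expect_equal(nrow(st$manifest), 7L)
  expect_true(min(st$manifest$rate[st$manifest$tag == "plast"]) >
                max(st$manifest$rate[st$manifest$tag == "mito"]))
  # shared topology: all true gene trees agree after restriction
  for (g in names(st$gene_trees)) {
    tt <- prune_to_taxa(st$true_trees[[st$tags[[g]]]],
                        st$gene_trees[[g]]$tip.label)
    expect_equal(rf_distance(tt, st$gene_trees[[g]]), 0L)
  }
  # determinism
  st2 <- simulate_organelle_study(cfg)
  expect_identical(unclass(st$genes[[1]]), unclass(st2$genes[[1]]))
  expect_identical(st$manifest, st2$manifest)

  # distinct topologies: RF at least the configured minimum
  cfg2 <- study_config(n_taxa = 10, n_plast = 2, n_mito = 2,
                       gene_sites = 200, topology = "distinct", min_rf = 4,
                       occupancy = 1, seed = 18)
  st3 <- simulate_organelle_study(cfg2)
  expect_gte(rf_distance(st3$true_trees$plast, st3$true_trees$mito), 4L)

  # round trip to disk
  d <- tempfile()
  write_study(st3, d)
  expect_true(file.exists(file.path(d, "manifest.tsv")))
  re <- read_fasta(file.path(d, paste0(names(st3$genes)[1], ".fasta")))
  expect_equal(unclass(re), unclass(st3$genes[[1]]))
})

test_that("dataset rate scaling shows up in fitted tree lengths", {
  cfg <- study_config(n_taxa = 8, n_plast = 3, n_mito = 3, rate_plast = 2,
                      rate_mito = 1, sigma_plast = 0.05, sigma_mito = 0.05,
                      gene_sites = 800, occupancy = 1, seed = 19)
  st <- simulate_organelle_study(cfg)
  tl <- vapply(names(st$genes), function(g) {
    fit <- fit_gtr(ape::unroot(st$gene_trees[[g]]), st$genes[[g]],
                   model = "GTR", free = "branch_lengths", tol = 0.1,
                   max_rounds = 4)
    tree_length(fit$tree)
  }, 0)
  ratio <- mean(tl[st$tags == "plast"]) / mean(tl[st$tags == "mito"])
  expect_lt(abs(ratio - 2) / 2, 0.2)
})
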