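# Bipartitions, support collapsing, RF distances, tree networks and layout.

test_that("bipartitions read off simple topologies", {
  bip <- bipartition_set(read_newick(text = "((a,b),c,(d,e));"))
  # canonical keys name the side away from the reference taxon "a"
  expect_setequal(names(bip$splits), c("c,d,e", "d,e"))
  expect_true(any(vapply(bip$splits, setequal, TRUE, y = c("d", "e"))))
  star <- read_newick(text = "(a,b,c,d,e);")
  expect_length(bipartition_set(star)$splits, 0L)
  # random binary 10-tip tree: n-3 pairwise compatible splits
  tr <- ape::unroot(sample_tree(10, seed = 71))
  bip10 <- bipartition_set(tr)
  expect_length(bip10$splits, 7L)
  for (i in seq_along(bip10$splits))
    for (j in seq_along(bip10$splits))
      expect_true(phylocomb:::splits_compatible(bip10$splits[[i]],
                                                bip10$splits[[j]],
                                                tr$tip.label))
})

test_that("support collapsing contracts exactly the weak edges", {
  tr <- read_newick(text = "((a:1,b:1)80:1,c:1,(d:1,e:1)97:1);")
  expect_equal(rf_distance(collapse_by_support(tr, 0), tr), 0L)
  c95 <- collapse_by_support(tr, 95)
  expect_setequal(names(bipartition_set(c95)$splits), "d,e")
  expect_length(bipartition_set(collapse_by_support(tr, 101))$splits, 0L)
  expect_setequal(c95$tip.label, tr$tip.label)
  # collapsed split set == splits meeting the threshold, on random trees
  for (seed in 1:5) {
    tr2 <- ape::unroot(sample_tree(8, seed = seed))
    set.seed(seed); sup <- round(runif(5, 0, 100))
    bip <- bipartition_set(tr2)
    tr2 <- phylocomb:::annotate_supports(tr2, bip,
      stats::setNames(sup[seq_along(bip$splits)], names(bip$splits)))
    thr <- 50
    kept <- names(bipartition_set(collapse_by_support(tr2, thr))$splits)
    bip2 <- bipartition_set(tr2)
    expect_setequal(kept, names(bip2$splits)[bip2$support >= thr])
  }
})

test_that("edges without supports collapse when a threshold is active", {
  tr <- read_newick(text = "((a,b),c,(d,e));")  # no supports at all
  expect_length(bipartition_set(collapse_by_support(tr, 95))$splits, 0L)
  expect_equal(rf_distance(tr, tr, support_threshold = 95), 0L)
})

test_that("RF distance matches brute-force symmetric difference everywhere", {
  t1 <- read_newick(text = "((a,b),c,(d,e));")
  t2 <- read_newick(text = "((a,c),b,(d,e));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)

  topo5 <- lapply(all_topologies(paste0("t", 1:5)),
                  function(x) read_newick(text = x))
  expect_length(topo5, 15L)
  splits5 <- lapply(topo5, function(tr) names(bipartition_set(tr)$splits))
  for (i in seq_along(topo5)) for (j in seq_along(topo5)) {
    brute <- length(setdiff(splits5[[i]], splits5[[j]])) +
      length(setdiff(splits5[[j]], splits5[[i]]))
    expect_identical(rf_distance(topo5[[i]], topo5[[j]]), brute)
    # cross-check against an independent implementation
    expect_equal(brute, as.integer(suppressWarnings(
      phangorn::RF.dist(topo5[[i]], topo5[[j]]))))
  }
  # metric axioms by brute force on all 5-tip triples
  D <- outer(seq_along(topo5), seq_along(topo5),
             Vectorize(function(i, j) rf_distance(topo5[[i]], topo5[[j]])))
  expect_true(all(D == t(D)))
  expect_true(all(diag(D) == 0))
  for (i in 1:15) for (j in 1:15) for (k in 1:15)
    if (D[i, k] > D[i, j] + D[j, k]) fail("triangle inequality violated")
  # RF <= 2(n-3), attained by split-disjoint pairs
  expect_true(max(D) <= 2 * (5 - 3))
  expect_true(any(D == 2 * (5 - 3)))
})

test_that("RF on 6-tip topologies agrees with the independent implementation", {
  topo6 <- lapply(all_topologies(paste0("t", 1:6)),
                  function(x) read_newick(text = x))
  expect_length(topo6, 105L)
  set.seed(8)
  idx <- cbind(sample(105, 300, TRUE), sample(105, 300, TRUE))
  for (r in seq_len(nrow(idx))) {
    a <- topo6[[idx[r, 1]]]; b <- topo6[[idx[r, 2]]]
    expect_identical(rf_distance(a, b),
                     as.integer(suppressWarnings(phangorn::RF.dist(a, b))))
  }
})

test_that("trees with unequal tip sets are pruned to the intersection", {
  t1 <- read_newick(text = "((a,b),c,((d,e),f));")
  t2 <- read_newick(text = "((a,b),c,(d,e));")
  expect_equal(rf_distance(t1, t2), 0L)
  expect_error(rf_distance(read_newick(text = "((a,b),(c,x));"),
                           read_newick(text = "((a,b),(y,z));")), "shared")
})

test_that("tree length sums branches and is rerooting-invariant", {
  expect_equal(tree_length(read_newick(text = "(a:1,b:2,c:3);")), 6)
  tr <- sample_tree(7, seed = 81)
  expect_equal(tree_length(ape::root(ape::unroot(tr), outgroup = "t3",
                                     resolve.root = FALSE)),
               tree_length(tr), tolerance = 1e-12)
  expect_error(tree_length(read_newick(text = "(a,b,c);")), "length")
})

test_that("tree networks merge identical topologies and weight by 1/RF", {
  t1 <- read_newick(text = "((a,b),c,(d,e));")
  t2 <- read_newick(text = "((a,b),c,(d,e));")
  t3 <- read_newick(text = "((a,c),b,(d,e));")
  net <- build_tree_network(list(x = t1, y = t2, z = t3))
  expect_length(net$nodes, 2L)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$rf, 2L)
  expect_equal(net$edges$weight, 0.5)
  expect_true(all(net$rf_matrix == t(net$rf_matrix)))
  expect_true(all(diag(net$rf_matrix) == 0))
  # node count + extra members = number of trees
  expect_equal(length(net$nodes) + sum(lengths(net$nodes) - 1L), 3L)
  # weights strictly decrease along an NNI ladder
  base <- ape::unroot(sample_tree(10, seed = 91))
  ladder <- list(t0 = base)
  cur <- base
  for (i in 1:3) {
    cur <- perturb_nni(cur, 1, seed = 90 + i)
    ladder[[paste0("t", i)]] <- cur
  }
  net2 <- build_tree_network(ladder)
  w <- net2$edges
  from0 <- w[w$from == "t0", ]
  if (nrow(from0) >= 2) expect_true(all(diff(from0$weight[order(from0$rf)]) < 0))
})

test_that("force-directed layout is deterministic and reaches equilibrium", {
  t1 <- read_newick(text = "((a,b),c,(d,e));")
  t3 <- read_newick(text = "((a,c),b,(d,e));")
  net1 <- build_tree_network(list(x = t1, y = t1))
  one <- fr_layout(net1)
  expect_equal(c(one$x, one$y), c(0, 0))
  net <- build_tree_network(list(x = t1, z = t3))
  l1 <- fr_layout(net, seed = 4)
  l2 <- fr_layout(net, seed = 4)
  expect_identical(l1, l2)
  expect_true(all(is.finite(c(l1$x, l1$y))))
  # two-node equilibrium: spacing approaches the ideal distance k
  l3 <- fr_layout(net, iterations = 500, seed = 4)
  d <- sqrt(diff(l3$x)^2 + diff(l3$y)^2)
  k <- sqrt(1 / 2)
  expect_lt(abs(d - k) / k, 0.2)
})
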