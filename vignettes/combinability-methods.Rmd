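---
title: "Partitioned-model combinability testing: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned-model combinability testing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylocomb)
```

## The question

Organellar genomes are usually inherited from one parent, so the plastid and
mitochondrial gene sets of the same taxa "should" tell one story. Whether
they actually do can be phrased as model selection: is the combined
supermatrix better explained by a model in which both gene sets share one
tree (possibly with partition-specific substitution parameters and rates),
or by two fully independent trees? `phylocomb` implements this comparison
and the companion analyses that localise and explain any disagreement.

## The substitution model

Each partition evolves under GTR+I+G. The rate matrix is
`q_ij = s_ij * pi_j` for `i != j`, with the six exchangeabilities
`s = (AC, AG, AT, CG, CT, GT)` scaled so `s_GT = 1` (5 free), base
frequencies `pi` (3 free, simplex), a proportion `p_inv` of invariant sites
and a gamma shape `alpha` discretised into 4 equal-probability categories
whose rates are the bin means of a Gamma(`alpha`, `alpha`) density (mean 1
by construction). `Q` is normalised so that one unit of branch length is one
expected substitution per site: `-sum(pi_i q_ii) = 1`. That gives 10 free
substitution parameters per partition — the count used everywhere in the
information criteria.

Likelihoods are computed by Felsenstein pruning over compressed site
patterns in compiled code. Gap and IUPAC-ambiguity characters are
marginalised: a tip contributes partial likelihood 1 over each state its
code allows, never a fifth state; an all-gap column therefore contributes
exactly zero log-likelihood. The invariant-site component of a pattern is
`sum(pi_s)` over the states all its tips allow.

## Linking schemes and parameter accounting

The five linking schemes form a nested ladder. With `p` partitions and `T`
taxa (unrooted tree, `2T - 3` branch lengths):

* unpartitioned: `k = 10 + (2T - 3)`;
* edge-equal: per-partition substitution parameters, shared lengths,
  `k = 10p + (2T - 3)`;
* edge-proportional: adds one rate multiplier per partition under the
  constraint that the site-count-weighted mean multiplier is 1, so it
  contributes `p - 1` free parameters. This constraint is the unique
  convention under which the parameter totals reproduce both the
  separate-topology worked example (`k = 2194 = 1317 + 877` for 79 + 39
  partitions on 226 taxa) and the BIC−AICc gaps of all three
  edge-proportional fits of the source study;
* edge-unlinked: free lengths per partition on one topology,
  `k = 10p + p(2T - 3)` — exactly the price of `p` separate trees, which is
  why it can never beat separate trees by an information criterion;
* separate trees: independent fits whose `lnL`, `n` and `k` are summed
  before AIC/AICc/BIC are computed. The component site counts must
  partition the full site set; the summation refuses inconsistent totals.

`AICc` uses `n` = total aligned sites. This is a deliberate, stated
convention (the natural alternative, effective sample size, is not
well-defined for partitioned alignments).

## Optimisation

Fitting is coordinate ascent: bounded Brent line searches over each free
substitution parameter on a transformed scale (log exchangeabilities, log
frequency ratios, log `alpha`, logit `p_inv`), a compiled branch-length
sweep, and — once the cyclic updates stall — a bounded quasi-Newton
(L-BFGS-B) polish. The branch sweep maintains directional partial
likelihoods so that each edge's one-dimensional optimisation costs one
pattern pass rather than a whole-tree pruning; edges are optimised by
golden-section search on the log scale within `[1e-8, 10]`
substitutions/site. Convergence is declared when a full round gains less
than `tol` (default `1e-4` nats); non-convergence is flagged on the result,
not raised. `polish = FALSE` skips the quasi-Newton stage; the large-margin
model comparisons in the test-suite use it because decision margins there
are tens to thousands of nats while the stage's gain is hundredths.

Warm starts matter for the nesting property: each richer linking scheme is
started at the optimum of the scheme it nests (edge-proportional from
edge-equal with unit multipliers, and so on). Because the optimiser only
ever accepts improvements, the fitted log-likelihoods are monotone along
the ladder by construction, whatever the convergence depth — the property
the test-suite asserts.

Edge-proportional multipliers are optimised freely and then renormalised to
weighted mean 1 with the inverse factor absorbed into the shared lengths, a
reparameterisation that leaves the likelihood unchanged.

## Greedy partition merging

Merging starts from one cluster per gene and scores every candidate pair
merge under the information criterion (default BIC) of the whole
edge-proportional model: the merged cluster refits its 10 substitution
parameters and its rate multiplier on the current shared branch lengths,
which are re-optimised once per round, not per pair — the pair scan is a
screen, and each accepted merge is confirmed by a full refit before it
counts. Ties break on the lexicographically smallest pair of cluster names.
The trace records each merge's criterion delta (always negative), and a
merge whose full refit fails to confirm the screened improvement is
reverted, so the final criterion never exceeds the initial one.

## Tree comparison and conflict

Robinson–Foulds distances are unweighted symmetric differences of
non-trivial split sets. With a support threshold, both trees first have
every internal edge below the threshold contracted; edges with no support
annotation count as support 0 when a threshold is active (a conservative,
declared convention). Trees on unequal taxon sets are pruned to the shared
taxa. Identical topologies are merged into one node of the tree network;
edges carry weight `1/RF`, so "infinite similarity" never appears as a
weight. The layout is the classic Fruchterman–Reingold scheme (attraction
`d^2/k`, repulsion `k^2/d`, linear cooling), deterministic given its seed.

Conflict mapping is bipartition-based. For each internal reference edge and
each gene tree, the reference split is restricted to the taxa shared with
the gene tree; if the restriction is trivial the gene is uninformative for
that edge. Otherwise the gene is concordant if it contains the restricted
split, in conflict if it contains an incompatible split (strength judged by
the most-supported incompatible split against the percent threshold,
default 95), and uninformative when merely unresolved — an
unresolved-but-compatible gene tree does not count as concordant. Reference
edges whose restrictions coincide are tallied independently.

## Clock metrics

Midpoint rooting places the root halfway along the longest tip-to-tip path;
root-to-tip variance is the sample variance (`n - 1` denominator, a
declared convention) of the root-to-tip path lengths, zero exactly for
clocklike genes. Pruning to a gene's taxon set preserves path lengths by
summing the branch lengths of suppressed degree-2 nodes; a surviving node
keeps its own support annotation.

## Compositional shifts

The shift model is deliberately explicit and simple: each tip's unambiguous
base counts are multinomial draws from the frequency vector of the
composition regime painted on its subtending edge. Regime 0 covers the
whole rooted tree; each added regime is introduced at one candidate edge
(internal, subtending at least `min_clade = 4` tips) and inherited by the
entire clade below, with nested shifts overriding by the nearest-ancestor
rule. Maximum-likelihood regime frequencies are pooled count proportions
(additive smoothing of 0.5 per cell only when a pooled count is zero), each
regime costs 3 free parameters, `n` is the total unambiguous base count,
and regimes are added greedily while the criterion (default BIC) improves,
up to `max_shifts = 10`. This captures the stated concept — clade-restricted
shifts in compositional heterogeneity on a fixed topology with a minimum
clade size — with a fully testable likelihood; it deliberately ignores
branch lengths, so very short branches separating genuinely different
regimes are harder to detect than a branch-length-aware non-stationary
model would find them. The simulator, by contrast, is branch-aware: below a
shift edge the full GTR matrix is rebuilt with the new frequencies, so
detection is tested against data *harder* than the detection model assumes.

## The synthetic study and what passing tests mean

`simulate_organelle_study()` emulates the study design at desk scale:
16 taxa, 8 higher-rate "plast" genes (dataset rate 2, multiplier sigma 0.3)
and 5 lower-rate "mito" genes (rate 1, sigma 0.6) of 1000 sites each, 90%
uniform taxon occupancy, shared or distinct (RF >= 4) true topologies, and
optional planted composition shifts. These defaults are fixed once: gene
counts and the rate/spread ordering mirror the two-compartment structure
(more, faster plastid genes; fewer, slower, more rate-dispersed
mitochondrial genes), while sizes are chosen so that model selection is
decisive yet a full study runs in minutes. The test-suite's heavier
property checks state their own sizes (for example 8 taxa x 3000 sites per
dataset for the combinability decision, 20 seeded replicates per
condition; 6 taxa x 400 sites per gene for merging; 16 taxa x 2000 sites
for shift recovery).

Passing these suites shows the machinery is correct and decision-consistent
under the generating model. Real organellar data differ in known ways the
generator does not emulate: structured (not uniform) occupancy, among-site
process heterogeneity beyond gamma, alignment error, RNA editing and
codon structure. Conclusions about real data should rest on the method,
not on the synthetic pass rates.

## Numerical conventions

* Branch lengths live in `[1e-8, 10]` substitutions/site; optimiser
  tolerance defaults to `1e-4` nats; at most 100 coordinate rounds.
* Discrete gamma uses category means over equal-probability bins.
* Base frequencies are ML-optimised from empirical starting values, so each
  partition prices 10 substitution parameters, matching the `k` convention.
* Supports are percentages; an input tree whose supports all lie in
  `[0, 1]` is assumed fractional and rescaled with a warning.
* Pattern compression is exact; likelihood scaling guards against
  underflow on long trees.
* Random seeds are explicit arguments everywhere; generators restore the
  caller's RNG state.
* The midpoint root is unique when the diameter path is unique; ties are
  resolved by the underlying deterministic traversal order.

## Known limitations

The topology search is greedy NNI hill-climbing from a neighbour-joining
start — adequate at desk scale, not a replacement for a full heuristic
search on hundreds of taxa. Bootstrap supports are plain nonparametric
(sites resampled with replacement, replicates re-searched), not the
ultrafast approximation used by large-scale tools; they are consumed only
as thresholds. The shift detector's multinomial likelihood is stationary
within regimes and blind to branch lengths, as discussed above. AICc's
sample-size convention (total sites) is a choice, not a theorem.
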