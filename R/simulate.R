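# Seeded generators reproducing the statistical structure of a two-organelle
# phylogenomic study: a shared taxon set, a "plast"-like gene set (more
# genes, higher substitution rate, narrower per-gene rate spread) and a
# "mito"-like set (fewer genes, lower rate, broader spread), with partial
# taxon occupancy and optional clade-restricted composition shifts. Every
# generator is a pure function of its seed.

#' Sample a random bifurcating tree
#'
#' Random coalescent-style joins of labelled lineages; branch lengths are
#' i.i.d. exponential with the given mean.
#'
#' @param n_taxa number of tips (>= 4).
#' @param seed RNG seed (mandatory).
#' @param mean_branch_length mean edge length (default 0.1
#'   substitutions/site).
#' @param labels optional tip labels (default `t1..tn`).
#' @return A rooted bifurcating `phylo` tree.
#' @export
sample_tree <- function(n_taxa, seed, mean_branch_length = 0.1,
                        labels = paste0("t", seq_len(n_taxa))) {
  stopifnot(n_taxa >= 4L, length(labels) == n_taxa)
  with_seed(seed, {
    nodes <- as.list(labels)
    repeat {
      if (length(nodes) == 1L) break
      pick <- sample.int(length(nodes), 2L)
      l <- stats::rexp(2L, rate = 1 / mean_branch_length)
      joined <- sprintf("(%s:%.10f,%s:%.10f)", nodes[[pick[1L]]], l[1L],
                        nodes[[pick[2L]]], l[2L])
      nodes[[pick[1L]]] <- joined
      nodes[[pick[2L]]] <- NULL
    }
    ape::read.tree(text = paste0(nodes[[1L]], ";"))
  })
}

# simulate tip states along a rooted (or basally multifurcating) tree under
# GTR+I+G with optional composition regimes per edge; returns nuc_alignment
.simulate_states <- function(tree, params, n_sites, seed,
                             shifts = NULL) {
  tree <- stats::reorder(canon_tree(tree), "cladewise")  # parents before children
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- tree$edge[1L, 1L]
  # per-edge regime: 1 = base; shifts = list(node =, freqs =)
  regime <- rep(1L, nnode)
  eigens <- list(gtr_eigen(params))
  freqs_of <- list(params$freqs)
  if (!is.null(shifts) && length(shifts)) {
    shift_nodes <- vapply(shifts, `[[`, 0L, "node")
    for (s in seq_along(shifts)) {
      pr <- gtr_params(rates = params$rates, freqs = shifts[[s]]$freqs,
                       p_inv = params$p_inv, alpha = params$alpha,
                       ncat = params$ncat)
      eigens[[s + 1L]] <- gtr_eigen(pr)
      freqs_of[[s + 1L]] <- pr$freqs
    }
  } else shift_nodes <- integer(0)
  with_seed(seed, {
    gam <- discrete_gamma_rates(params$alpha, params$ncat)
    cat_of <- sample.int(params$ncat, n_sites, replace = TRUE)
    invariant <- stats::runif(n_sites) < params$p_inv
    rate_of <- ifelse(invariant, 0, gam[cat_of])
    states <- matrix(0L, nnode, n_sites)
    states[root, ] <- sample.int(4L, n_sites, replace = TRUE,
                                 prob = params$freqs)
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
      hit <- match(ch, shift_nodes)
      regime[ch] <- if (!is.na(hit)) hit + 1L else regime[p]
      eg <- eigens[[regime[ch]]]
      t_e <- tree$edge.length[e]
      for (r in unique(rate_of)) {
        idx <- which(rate_of == r)
        if (!length(idx)) next
        if (r == 0 || t_e == 0) {
          states[ch, idx] <- states[p, idx]
        } else {
          P <- eg$vectors %*% (exp(eg$values * r * t_e) * eg$inv)
          P[P < 0] <- 0
          for (s in 1:4) {
            here <- idx[states[p, idx] == s]
            if (length(here))
              states[ch, here] <- sample.int(4L, length(here),
                                             replace = TRUE, prob = P[s, ])
          }
        }
      }
    }
    m <- matrix(c("A", "C", "G", "T")[states[seq_len(ntip), ]], nrow = ntip)
    rownames(m) <- tree$tip.label
    nuc_alignment(m)
  })
}

#' Simulate an alignment along a tree
#'
#' Root states are drawn from the stationary frequencies; states evolve
#' edge-wise under the GTR transition kernel with per-site
#' invariant/gamma-category rates. Deterministic given `seed`.
#'
#' @param tree `phylo` tree with branch lengths.
#' @param params a [gtr_params()] object.
#' @param n_sites number of sites.
#' @param seed RNG seed (mandatory).
#' @return A [nuc_alignment()].
#' @export
simulate_alignment <- function(tree, params, n_sites, seed) {
  .simulate_states(tree, params, n_sites, seed, shifts = NULL)
}

#' Simulate an alignment with clade-restricted composition shifts
#'
#' Below each shift edge the rate matrix is rebuilt with the new base
#' frequencies (same exchangeabilities, re-normalised), making the process
#' non-stationary by construction. With no shifts the output is identical to
#' [simulate_alignment()] for the same seed.
#'
#' @param tree rooted `phylo` tree with branch lengths.
#' @param shifts list of `list(node =, freqs =)` entries: the child node of
#'   each shift edge and the new frequency vector.
#' @param params base [gtr_params()].
#' @param n_sites number of sites.
#' @param seed RNG seed.
#' @return A [nuc_alignment()].
#' @export
simulate_composition_shift_alignment <- function(tree, shifts, params,
                                                 n_sites, seed) {
  for (s in shifts) {
    if (length(s$freqs) != 4L || any(s$freqs <= 0))
      stop("invalid shift frequency vector")
  }
  .simulate_states(tree, params, n_sites, seed, shifts = shifts)
}

#' Apply random NNI moves to a tree
#'
#' @param tree bifurcating `phylo` tree.
#' @param n_moves number of random nearest-neighbour interchanges (>= 0).
#' @param seed RNG seed.
#' @return A `phylo` tree whose RF distance to the input is at most
#'   `2 * n_moves`.
#' @export
perturb_nni <- function(tree, n_moves, seed) {
  stopifnot(n_moves >= 0L)
  if (n_moves == 0L) return(tree)
  el <- tree$edge.length
  with_seed(seed, {
    cur <- tree
    for (i in seq_len(n_moves)) {
      nbrs <- phangorn::nni(stats::reorder(canon_tree(cur), "cladewise"))
      cur <- canon_tree(nbrs[[sample.int(length(nbrs), 1L)]])
    }
    if (!is.null(el) && is.null(cur$edge.length))
      cur$edge.length <- rep(mean(el), nrow(cur$edge))
    cur
  })
}

#' Configuration of a synthetic two-organelle study
#'
#' Defaults reproduce the study structure at desk scale: 16 taxa, 8
#' higher-rate "plast" genes with narrow per-gene rate spread and 5
#' lower-rate "mito" genes with broad spread, 1000 sites per gene, 90%
#' taxon occupancy.
#'
#' @param n_taxa taxon count.
#' @param n_plast,n_mito gene counts per dataset tag.
#' @param rate_plast,rate_mito dataset-level branch-length rate multipliers
#'   (plast > mito mirrors the faster plastome).
#' @param sigma_plast,sigma_mito log-normal sigma of per-gene rate
#'   multipliers (mito > plast mirrors the broader mitochondrial spread).
#' @param gene_sites sites per gene (scalar or per-gene vector).
#' @param occupancy fraction of taxa present per gene, in (0, 1].
#' @param topology `"shared"` or `"distinct"`; distinct draws a second true
#'   topology for the mito genes at least `min_rf` RF from the first.
#' @param min_rf minimum RF distance between the two true topologies.
#' @param mean_branch_length mean branch length of the base tree before rate
#'   scaling.
#' @param shifts optional list of planted composition shifts
#'   (`list(gene =, node =, freqs =)`).
#' @param seed RNG seed (mandatory).
#' @return A `study_config` list.
#' @export
study_config <- function(n_taxa = 16L, n_plast = 8L, n_mito = 5L,
                         rate_plast = 2, rate_mito = 1,
                         sigma_plast = 0.3, sigma_mito = 0.6,
                         gene_sites = 1000L, occupancy = 0.9,
                         topology = c("shared", "distinct"), min_rf = 4L,
                         mean_branch_length = 0.05, shifts = NULL, seed) {
  topology <- match.arg(topology)
  stopifnot(rate_plast > 0, rate_mito > 0, occupancy > 0, occupancy <= 1,
            n_plast >= 1L, n_mito >= 1L, !missing(seed))
  structure(list(n_taxa = as.integer(n_taxa), n_plast = as.integer(n_plast),
                 n_mito = as.integer(n_mito), rate_plast = rate_plast,
                 rate_mito = rate_mito, sigma_plast = sigma_plast,
                 sigma_mito = sigma_mito, gene_sites = gene_sites,
                 occupancy = occupancy, topology = topology,
                 min_rf = as.integer(min_rf),
                 mean_branch_length = mean_branch_length,
                 shifts = shifts, seed = as.integer(seed)),
            class = "study_config")
}

#' Simulate a two-organelle gene-set study
#'
#' Draws the true topology (or two topologies), per-gene rate multipliers,
#' alignments and occupancy dropout, and records every generating truth in
#' the manifest.
#'
#' @param config a [study_config()].
#' @return List of class `organelle_study`: `genes` (named list of
#'   alignments), `tags` (dataset tag per gene), `gene_trees` (true scaled
#'   trees per gene), `true_trees` (per tag), and `manifest` (data frame of
#'   generating truths).
#' @export
simulate_organelle_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  cfg <- config
  base_tree <- sample_tree(cfg$n_taxa, seed = cfg$seed,
                           mean_branch_length = cfg$mean_branch_length)
  tree_mito <- base_tree
  if (cfg$topology == "distinct") {
    s <- cfg$seed
    repeat {
      s <- s + 1L
      cand <- perturb_nni(base_tree, max(2L, cfg$min_rf %/% 2L + 1L), seed = s)
      cand <- with_seed(s + 1000L, {
        cand$edge.length <- stats::rexp(nrow(cand$edge),
                                        rate = 1 / cfg$mean_branch_length)
        cand
      })
      if (rf_distance(base_tree, cand) >= cfg$min_rf) { tree_mito <- cand; break }
    }
  }
  true_trees <- list(plast = base_tree, mito = tree_mito)
  n_genes <- cfg$n_plast + cfg$n_mito
  tags <- c(rep("plast", cfg$n_plast), rep("mito", cfg$n_mito))
  gene_names <- c(paste0("pt", seq_len(cfg$n_plast)),
                  paste0("mt", seq_len(cfg$n_mito)))
  sites <- rep_len(cfg$gene_sites, n_genes)
  mult <- with_seed(cfg$seed + 1L, {
    sig <- ifelse(tags == "plast", cfg$sigma_plast, cfg$sigma_mito)
    stats::rlnorm(n_genes, meanlog = -sig^2 / 2, sdlog = sig)
  })
  rate <- ifelse(tags == "plast", cfg$rate_plast, cfg$rate_mito)
  genes <- list(); gene_trees <- list()
  shift_of <- rep("", n_genes)
  for (g in seq_len(n_genes)) {
    tr <- true_trees[[tags[g]]]
    tr$edge.length <- tr$edge.length * rate[g] * mult[g]
    keep <- with_seed(cfg$seed + 100L + g, {
      k <- tr$tip.label[stats::runif(cfg$n_taxa) <= cfg$occupancy]
      while (length(k) < 4L)  # a gene needs enough taxa to be usable
        k <- tr$tip.label[stats::runif(cfg$n_taxa) <= cfg$occupancy]
      k
    })
    tr_g <- if (length(keep) < cfg$n_taxa) prune_to_taxa(tr, keep) else tr
    planted <- Filter(function(s) s$gene == gene_names[g], cfg$shifts %||% list())
    aln <- if (length(planted)) {
      simulate_composition_shift_alignment(
        tr_g, lapply(planted, function(s) s[c("node", "freqs")]),
        gtr_params(freqs = c(0.3, 0.2, 0.2, 0.3), alpha = 1),
        sites[g], seed = cfg$seed + 500L + g)
    } else {
      simulate_alignment(tr_g, gtr_params(freqs = c(0.3, 0.2, 0.2, 0.3),
                                          alpha = 1),
                         sites[g], seed = cfg$seed + 500L + g)
    }
    if (length(planted)) shift_of[g] <- paste(
      vapply(planted, function(s) as.character(s$node), ""), collapse = ";")
    genes[[gene_names[g]]] <- aln
    gene_trees[[gene_names[g]]] <- tr_g
  }
  manifest <- data.frame(gene = gene_names, tag = tags,
                         n_sites = sites, rate = rate, multiplier = mult,
                         n_taxa = vapply(genes, nrow, 0L),
                         shifts = shift_of, row.names = NULL)
  structure(list(genes = genes, tags = stats::setNames(tags, gene_names),
                 gene_trees = gene_trees, true_trees = true_trees,
                 manifest = manifest, config = cfg),
            class = "organelle_study")
}

#' @export
print.organelle_study <- function(x, ...) {
  cat("Synthetic organelle study:", length(x$genes), "genes (",
      sum(x$tags == "plast"), "plast,", sum(x$tags == "mito"), "mito ) on",
      x$config$n_taxa, "taxa;", x$config$topology, "topology\n")
  invisible(x)
}

#' Write a study to a directory (FASTA per gene, true trees, manifest)
#' @param study an `organelle_study`.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (g in names(study$genes))
    write_fasta(study$genes[[g]], file.path(dir, paste0(g, ".fasta")))
  for (tg in names(study$true_trees))
    write_newick(study$true_trees[[tg]],
                 file.path(dir, paste0("true_", tg, ".nwk")))
  utils::write.table(study$manifest, file.path(dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
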