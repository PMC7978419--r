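# Synthetic clade-structured data: trees with the empirical long/short
# branch contrast, Dirichlet profile libraries, and multi-gene datasets.

#' Configuration for a clade-structured tree
#'
#' Describes a five-clan tree (Outgroup, Lophotrochozoa, Ecdysozoa,
#' Chordata, Xenambulacraria) with a contested short stem on the
#' deuterostome side and a longer protostome stem, and the empirical
#' within-clan rate contrast (long outgroup/protostome branches, short
#' chordate/xenambulacrarian branches).
#'
#' @param taxa_per_clan Taxa per clan (>= 2); 4 gives a 20-tip tree.
#' @param topology Generating arrangement: `"DM"` (monophyletic
#'   deuterostomes), `"D1"` (Xenambulacraria sister to Protostomia), or
#'   `"D2"` (Chordata sister to Protostomia).
#' @param stem_deut Length of the contested deuterostome-side stem (the
#'   branch from the bilaterian ancestor toward Chordata+Xenambulacraria
#'   under DM, or toward the Xenambulacraria/Chordata + Protostomia group
#'   under D1/D2).
#' @param stem_prot Length of the protostome stem branch.
#' @param depth_multipliers Named per-clan multipliers of the mean
#'   within-clan root-to-tip depth.
#' @param base_depth Mean within-clan tip depth before multipliers.
#' @param depth_spread Lognormal sd (log scale) of per-taxon depth
#'   variation within a clan, emulating the strong among-taxon rate
#'   inequality of real datasets (0 gives clock-like clans).
#' @param clan_stem Length of the branch subtending each clan subtree.
#' @param bilateria_stem Branch from the root to the bilaterian ancestor.
#' @param outgroup_stem Branch from the root to the outgroup subtree.
#' @param seed Integer seed controlling the random within-clan subtrees.
#' @return A `clade_tree_config` list.
#' @export
clade_tree_config <- function(taxa_per_clan = 4L,
                              topology = c("DM", "D1", "D2"),
                              stem_deut = 0.01, stem_prot = 0.05,
                              depth_multipliers = c(Outgroup = 1.2,
                                                    Lophotrochozoa = 1,
                                                    Ecdysozoa = 1,
                                                    Chordata = 0.35,
                                                    Xenambulacraria = 0.35),
                              base_depth = 0.9, depth_spread = 0.5,
                              clan_stem = 0.15,
                              bilateria_stem = 0.3, outgroup_stem = 0.3,
                              seed = 1L) {
  topology <- match.arg(topology)
  if (taxa_per_clan < 2L)
    stop_invalid("taxa_per_clan must be >= 2 (clan MRCAs undefined)")
  stopifnot(stem_deut > 0, stem_prot > 0, base_depth > 0, clan_stem > 0,
            depth_spread >= 0)
  structure(list(taxa_per_clan = as.integer(taxa_per_clan),
                 topology = topology, stem_deut = stem_deut,
                 stem_prot = stem_prot,
                 depth_multipliers = depth_multipliers,
                 base_depth = base_depth, depth_spread = depth_spread,
                 clan_stem = clan_stem,
                 bilateria_stem = bilateria_stem,
                 outgroup_stem = outgroup_stem, seed = as.integer(seed)),
            class = "clade_tree_config")
}

# Random non-ultrametric clan subtree scaled to a target mean tip depth,
# with lognormal per-taxon depth spread applied through the terminal
# branches (long and short taxa within the same clan, as in real data).
clan_subtree <- function(n, labels, mean_depth, depth_spread = 0) {
  tr <- ape::rtree(n, rooted = TRUE, tip.label = labels)
  d <- ape::node.depth.edgelength(tr)[seq_len(n)]
  tr$edge.length <- tr$edge.length * mean_depth / mean(d)
  if (depth_spread > 0) {
    mult <- rlnorm(n, 0, depth_spread)
    mult <- mult / mean(mult)
    d <- ape::node.depth.edgelength(tr)[seq_len(n)]
    inner <- d - tr$edge.length[match(seq_len(n), tr$edge[, 2L])]
    target <- pmax(mean(d) * mult, inner + 0.02 * mean_depth)
    tr$edge.length[match(seq_len(n), tr$edge[, 2L])] <- target - inner
  }
  tr
}

#' Build a clade-structured tree and its clan map
#'
#' Within-clan subtrees are random (topology and branch lengths), scaled so
#' their mean tip depths follow the configured clan multipliers; the
#' backbone follows the requested DM/D1/D2 arrangement with the configured
#' stem lengths. Deterministic given `config$seed`.
#'
#' @param config A [clade_tree_config()].
#' @return List with elements `tree` (rooted `phylo`) and `clade_map`.
#' @export
make_clade_tree <- function(config) {
  stopifnot(inherits(config, "clade_tree_config"))
  n <- config$taxa_per_clan
  labels <- list(Outgroup = paste0("O", seq_len(n)),
                 Lophotrochozoa = paste0("L", seq_len(n)),
                 Ecdysozoa = paste0("E", seq_len(n)),
                 Chordata = paste0("C", seq_len(n)),
                 Xenambulacraria = paste0("X", seq_len(n)))
  spread <- config$depth_spread %||% 0
  sub <- with_seed(config$seed, {
    lapply(names(labels), function(cl) {
      clan_subtree(n, labels[[cl]],
                   config$base_depth * config$depth_multipliers[[cl]],
                   spread)
    })
  })
  names(sub) <- names(labels)
  nwk <- vapply(sub, function(tr) sub("\\);?$", ")",
                                      sub("^\\(", "(",
                                          write_newick(tr))), character(1L))
  nwk <- vapply(nwk, function(s) sub(";$", "", s), character(1L))
  cs <- config$clan_stem
  d <- config$stem_deut
  p <- config$stem_prot
  prot <- sprintf("(%s:%g,%s:%g):%g", nwk[["Lophotrochozoa"]], cs,
                  nwk[["Ecdysozoa"]], cs, p)
  backbone <- switch(config$topology,
    DM = sprintf("(%s,(%s:%g,%s:%g):%g)", prot, nwk[["Chordata"]], cs,
                 nwk[["Xenambulacraria"]], cs, d),
    D1 = sprintf("(%s:%g,(%s:%g,%s):%g)", nwk[["Chordata"]], cs,
                 nwk[["Xenambulacraria"]], cs, prot, d),
    D2 = sprintf("(%s:%g,(%s:%g,%s):%g)", nwk[["Xenambulacraria"]], cs,
                 nwk[["Chordata"]], cs, prot, d))
  full <- sprintf("(%s:%g,%s:%g);", nwk[["Outgroup"]],
                  config$outgroup_stem, backbone, config$bilateria_stem)
  tree <- parse_newick(full)
  cm <- clade_map(labels$Outgroup, labels$Lophotrochozoa, labels$Ecdysozoa,
                  labels$Chordata, labels$Xenambulacraria)
  list(tree = tree, clade_map = cm)
}

#' Random profile library
#'
#' `K` amino-acid frequency profiles drawn from a symmetric Dirichlet; small
#' concentrations give sparse, CAT-like profiles dominated by a few
#' residues.
#'
#' @param K Number of profiles (>= 1).
#' @param concentration Dirichlet concentration (default 0.2).
#' @param seed Integer seed.
#' @return K x 20 row-stochastic matrix.
#' @export
make_profile_library <- function(K, concentration = 0.2, seed = 1L) {
  if (K < 1L) stop_invalid("K must be >= 1")
  if (concentration <= 0) stop_invalid("concentration must be positive")
  with_seed(seed, {
    g <- matrix(rgamma(K * 20L, shape = concentration), K, 20L)
    g / rowSums(g)
  })
}

#' Configuration for a synthetic gene set
#'
#' @param n_genes Number of genes.
#' @param length_median Median alignment length (lognormal lengths,
#'   truncated below at `min_length`).
#' @param length_sdlog Lognormal sd of the length distribution (log scale).
#' @param rate_sdlog Lognormal sd of the per-gene rate multiplier (median
#'   1).
#' @param occupancy Probability that a taxon is present in a gene.
#' @param min_length Minimum gene length.
#' @param seed Integer base seed; gene `g` uses `seed + g`.
#' @return A `gene_set_config` list.
#' @export
gene_set_config <- function(n_genes, length_median = 300,
                            length_sdlog = 0.6, rate_sdlog = 0.4,
                            occupancy = 0.8, min_length = 50L, seed = 1L) {
  stopifnot(n_genes >= 1, occupancy > 0, occupancy <= 1, min_length >= 1)
  structure(list(n_genes = as.integer(n_genes),
                 length_median = length_median,
                 length_sdlog = length_sdlog, rate_sdlog = rate_sdlog,
                 occupancy = occupancy, min_length = as.integer(min_length),
                 seed = as.integer(seed)),
            class = "gene_set_config")
}

#' Simulate a multi-gene dataset
#'
#' Each gene is simulated on the tree with its branch lengths scaled by a
#' lognormal per-gene rate multiplier; taxon occupancy is applied by
#' deleting taxa at random, never emptying a clan when a clan map is
#' supplied. Deterministic given `config$seed`.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param model A [subst_model()].
#' @param config A [gene_set_config()].
#' @param cm Optional [clade_map()] used to protect one taxon per clan.
#' @return A list of [aa_alignment()] objects named `gene001`, ...
#' @export
make_geneset <- function(tree, model, config, cm = NULL) {
  stopifnot(inherits(config, "gene_set_config"))
  meta <- with_seed(config$seed, {
    len <- pmax(config$min_length,
                round(rlnorm(config$n_genes, log(config$length_median),
                             config$length_sdlog)))
    rate <- rlnorm(config$n_genes, 0, config$rate_sdlog)
    keep <- lapply(seq_len(config$n_genes), function(g) {
      tips <- tree$tip.label
      kp <- tips[runif(length(tips)) <= config$occupancy]
      if (!is.null(cm)) {
        for (cl in names(cm)) {
          pres <- intersect(cm[[cl]], tips)
          if (length(pres) && !length(intersect(kp, pres)))
            kp <- c(kp, sample(pres, 1L))
        }
      }
      if (length(kp) < 2L) kp <- sample(tips, 2L)
      kp
    })
    list(len = len, rate = rate, keep = keep)
  })
  genes <- vector("list", config$n_genes)
  for (g in seq_len(config$n_genes)) {
    aln <- simulate_alignment(tree, model, meta$len[g],
                              seed = config$seed + g,
                              rate_multiplier = meta$rate[g],
                              name = sprintf("gene%03d", g))
    genes[[g]] <- crop_alignment(aln, meta$keep[[g]])
  }
  names(genes) <- vapply(genes, attr, character(1L), "name")
  genes
}
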