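test_that("collapse statistic is nonnegative and small under the null", {
  # Data generated with an (effectively) zero focal stem: the collapsed
  # model is true, so the median delta-lnL over replicates stays below
  # half a nat.
  cfg <- clade_tree_config(taxa_per_clan = 2, stem_deut = 1e-8,
                           seed = 21)
  gen <- make_clade_tree(cfg)
  m <- lg_model(alpha = 1, ncat = 4)
  deltas <- vapply(1:5, function(r) {
    aln <- simulate_alignment(gen$tree, m, 4000, seed = 500 + r)
    d <- delta_lnl_collapse(aln, gen$tree, gen$clade_map,
                            "Deuterostomia", m)
    d$delta_lnl
  }, numeric(1))
  expect_true(all(deltas >= -1e-3))
  expect_lt(median(deltas), 0.5)
})

test_that("delta-lnL tracks the generating stem length", {
  stems <- c(1e-8, 0.005, 0.02, 0.08)
  m <- lg_model(alpha = 1, ncat = 4)
  grid <- expand.grid(stem = stems, rep = 1:3)
  res <- mapply(function(stem, rep) {
    cfg <- clade_tree_config(taxa_per_clan = 2, stem_deut = stem,
                             seed = 3)
    gen <- make_clade_tree(cfg)
    aln <- simulate_alignment(gen$tree, m, 6000, seed = 3000 + rep +
                                round(stem * 1e5))
    d <- delta_lnl_collapse(aln, gen$tree, gen$clade_map,
                            "Deuterostomia", m, tol = 1e-3)
    c(d$delta_lnl, d$stem_length)
  }, grid$stem, grid$rep)
  rho <- cor(grid$stem, res[1, ], method = "spearman")
  expect_gt(rho, 0.9)
  # Stem length and delta-lnL agree in sign of evidence.
  expect_gt(cor(res[2, ], res[1, ], method = "spearman"), 0.9)
})

test_that("per-gene tables favor the longer protostome stem", {
  cfg <- clade_tree_config(taxa_per_clan = 3, seed = 5)
  gen <- make_clade_tree(cfg)
  prof <- make_profile_library(10, 0.2, seed = 5)
  gmod <- subst_model(prof, alpha = 0.7, ncat = 4)
  genes <- make_geneset(gen$tree, gmod,
                        gene_set_config(n_genes = 20, seed = 5),
                        cm = gen$clade_map)
  # Score stems under the matched (generating) model: the construction
  # d < p is then recovered per gene.  Under a site-homogeneous model the
  # misspecification bias inflates the deuterostome stem instead (the
  # model-ladder effect tested below).
  m <- gmod
  tab <- per_gene_branch_table(genes, gen$tree, gen$clade_map, m)
  wide <- reshape(tab, idvar = "unit", timevar = "clade",
                  direction = "wide")
  frac <- mean(wide$stem_length.Protostomia >
                 wide$stem_length.Deuterostomia)
  expect_gt(frac, 0.5)
  expect_true(all(tab$delta_lnl >= -1e-3))
  # Self-consistency: length-weighted mean per-gene stems approximate the
  # concatenated-matrix analysis.
  conc <- concat_alignments(genes)
  fit <- optimize_branch_lengths(conc,
                                 root_on_outgroup(gen$tree,
                                                  gen$clade_map), m,
                                 tol = 1e-3, max_passes = 25)
  p_conc <- stem_branch_length(fit$tree, gen$clade_map, "Protostomia")
  lens <- vapply(genes, ncol, integer(1))[wide$unit]
  p_genes <- sum(wide$stem_length.Protostomia * lens) / sum(lens)
  expect_lt(abs(p_genes - p_conc) / p_conc, 0.35)
})

test_that("genes missing clan representation are skipped with reasons", {
  cfg <- clade_tree_config(taxa_per_clan = 2, seed = 7)
  gen <- make_clade_tree(cfg)
  m <- lg_model()
  aln <- simulate_alignment(gen$tree, m, 60, seed = 8)
  g_ok <- aa_alignment(unclass(aln), name = "ok")
  g_bad <- crop_alignment(aln, setdiff(rownames(aln), c("C1", "C2",
                                                        "X1")))
  attr(g_bad, "name") <- "bad"
  tab <- suppressWarnings(
    per_gene_branch_table(list(g_ok, g_bad), gen$tree, gen$clade_map, m,
                          max_passes = 5))
  expect_setequal(unique(tab$unit), "ok")
  expect_match(attr(tab, "skipped")[["bad"]], "deuterostome")
})

test_that("clade depth summary matches hand-computed worked values", {
  tr <- worked_tree()
  cm <- worked_map()
  d <- clade_depth_summary(tr, cm)
  get <- function(g) d$mean_depth[d$group == g]
  expect_equal(get("Protostomia"), 1.4)
  expect_equal(get("Chordata"), 1.3)
  expect_equal(get("Xenambulacraria"), 1.3)
  expect_equal(get("Outgroup"), 2.3)
  expect_warning(
    clade_depth_summary(crop_tree(tr, c("P1", "P2", "C1", "C2", "O1")),
                        cm), "Xenambulacraria")
})

test_that("dataset rate scales with the generating tree length", {
  set.seed(31)
  tr <- ape::rtree(8)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.3)
  tr2 <- tr
  tr2$edge.length <- tr$edge.length * 2
  m <- lg_model(alpha = 1, ncat = 4)
  a1 <- simulate_alignment(tr, m, 4000, seed = 32)
  a2 <- simulate_alignment(tr2, m, 4000, seed = 33)
  taxa8 <- tr$tip.label
  r1 <- dataset_rate(a1, tr, taxa8, m, tol = 1e-3)
  r2 <- dataset_rate(a2, tr, taxa8, m, tol = 1e-3)
  expect_lt(abs(r2 / r1 - 2), 0.2)
  # Invariance to the order of the common taxon set.
  expect_equal(dataset_rate(a1, tr, rev(taxa8), m, tol = 1e-3), r1,
               tolerance = 1e-6)
  # Near-zero rate for identical sequences.
  const <- aa_alignment(setNames(rep(paste(rep("A", 50), collapse = ""),
                                     8), taxa8))
  expect_lt(dataset_rate(const, tr, taxa8, m, tol = 1e-3), 1e-4)
  expect_error(dataset_rate(a1, tr, c(taxa8[1:3], "zz"), m), "missing")
})

test_that("better-fitting models shrink the contested stem estimate", {
  # Site-heterogeneous data: the single-profile fit overestimates the
  # deuterostome stem relative to the matched mixture fit.
  prof <- make_profile_library(10, 0.2, seed = 35)
  gmod <- subst_model(prof, alpha = 0.7, ncat = 4)
  cfg <- clade_tree_config(taxa_per_clan = 2, seed = 35)
  gen <- make_clade_tree(cfg)
  wins <- vapply(1:10, function(r) {
    aln <- simulate_alignment(gen$tree, gmod, 1500, seed = 700 + r)
    f_lg <- fit_model(aln, gen$tree, "LG", max_passes = 20)
    f_mix <- fit_model(aln, gen$tree, "MIX+LG+G", profiles = prof,
                       max_outer = 2, max_passes = 15)
    s_lg <- stem_branch_length(f_lg$tree, gen$clade_map,
                               "Deuterostomia")
    s_mix <- stem_branch_length(f_mix$tree, gen$clade_map,
                                "Deuterostomia")
    s_mix < s_lg
  }, logical(1))
  expect_gte(sum(wins), 8)
})
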