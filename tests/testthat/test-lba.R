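test_that("selection picks the generating topology in an easy regime", {
  cfg <- clade_tree_config(taxa_per_clan = 2, stem_deut = 0.3,
                           stem_prot = 0.3, seed = 3)
  gen <- make_clade_tree(cfg)
  m <- lg_model(alpha = 1, ncat = 4)
  hyp <- hypothesis_trees(gen$tree, gen$clade_map, "deuterostome")
  aln <- simulate_alignment(gen$tree, m, 3000, seed = 4)
  sel <- select_topology(aln, hyp, m)
  expect_equal(as.character(sel), "DM")
  expect_false(attr(sel, "tie"))
})

test_that("exact ties resolve to the first label and are flagged", {
  gen <- make_clade_tree(clade_tree_config(taxa_per_clan = 2, seed = 5))
  const <- aa_alignment(setNames(rep(strrep("AR", 20),
                                     length(gen$tree$tip.label)),
                                 gen$tree$tip.label))
  hyp <- hypothesis_trees(gen$tree, gen$clade_map, "deuterostome")
  m <- lg_model()
  sel <- select_topology(const, hyp, m)
  expect_equal(as.character(sel), "DM")
  expect_true(attr(sel, "tie"))
})

test_that("taxon removal ranks depths and protects clans", {
  tr <- parse_newick(paste0(
    "(((L1:2,L2:0.2):0.1,(E1:1.5,E2:0.3):0.1):0.05,",
    "((C1:0.3,C2:0.3):0.1,(X1:0.3,X2:0.3):0.1):0.05,",
    "(O1:3,O2:0.5):0.4);"))
  cm <- clade_map(c("O1", "O2"), c("L1", "L2"), c("E1", "E2"),
                  c("C1", "C2"), c("X1", "X2"))
  expect_equal(taxon_removal_sets(tr, cm, 0, "longest"), character())
  # The three constructed long arms, in depth order.
  expect_setequal(taxon_removal_sets(tr, cm, 3, "longest"),
                  c("O1", "L1", "E1"))
  expect_setequal(taxon_removal_sets(tr, cm, 3, "shortest"),
                  c("L2", "E2", "O2"))
  # Never empties a clan: with k = 3 per-clan singletons survive.
  rem <- taxon_removal_sets(tr, cm, 3, "longest")
  kept <- setdiff(tr$tip.label, rem)
  for (cl in c("Outgroup", "Lophotrochozoa", "Ecdysozoa"))
    expect_gte(length(intersect(kept, cm[[cl]])), 1L)
  expect_error(taxon_removal_sets(tr, cm, 5, "longest"), "exceeds")
  # Clan protection can make k unreachable.
  expect_error(taxon_removal_sets(tr, cm, 4, "longest"),
               "keeping every clan")
  # Deuterostome taxa are never candidates.
  expect_false(any(grepl("^[CX]", taxon_removal_sets(tr, cm, 3,
                                                     "longest"))))
})

test_that("removal sets on the default generator keep clans covered", {
  gen <- make_clade_tree(clade_tree_config(seed = 23))
  k <- 6
  for (mode in c("longest", "shortest")) {
    rem <- taxon_removal_sets(gen$tree, gen$clade_map, k, mode)
    expect_length(rem, k)
    kept <- setdiff(gen$tree$tip.label, rem)
    for (cl in names(gen$clade_map))
      expect_gte(length(intersect(kept, gen$clade_map[[cl]])), 1L)
  }
  long <- taxon_removal_sets(gen$tree, gen$clade_map, k, "longest")
  short <- taxon_removal_sets(gen$tree, gen$clade_map, k, "shortest")
  d <- root_to_tip_lengths(gen$tree, gen$clade_map)
  expect_gt(mean(d[long]), mean(d[short]))
})

test_that("a small experiment conserves tallies and logs replicates", {
  cfg <- lba_config(topologies = c("DM", "D1"), n_replicates = 2,
                    n_sites = 250,
                    tree_config = clade_tree_config(taxa_per_clan = 3),
                    conditions = c("Hom", "HomNL", "HomNS"),
                    max_passes = 6)
  tally <- run_lba_experiment(cfg)
  for (gt in c("DM", "D1"))
    for (cond in c("Hom", "HomNL", "HomNS"))
      expect_equal(sum(tally$counts[gt, cond, ]), 2L)
  expect_equal(nrow(tally$log), 2L * 2L * 3L)
  expect_true(all(tally$log$selected %in% c("DM", "D1", "D2")))
  # Determinism: identical configuration reproduces the tally.
  tally2 <- run_lba_experiment(cfg)
  expect_identical(tally$counts, tally2$counts)
  expect_equal(tally$log$lnl_DM, tally2$log$lnl_DM, tolerance = 1e-9)
  expect_equal(recovery_percent(tally, "DM", "Hom", "DM"),
               100 * tally$counts["DM", "Hom", "DM"] / 2)
})

test_that("cross-validation ranks the model ladder on mixture data", {
  prof <- make_profile_library(8, 0.2, seed = 29)
  gmod <- subst_model(prof, alpha = 0.7, ncat = 4)
  gen <- make_clade_tree(clade_tree_config(taxa_per_clan = 2,
                                           seed = 29))
  aln <- simulate_alignment(gen$tree, gmod, 4000, seed = 29)
  cv <- cross_validation(aln, gen$tree,
                         models = c("LG", "LG+G", "MIX+LG+G"),
                         profiles = prof, n_folds = 3,
                         train_sites = 1500, test_sites = 500,
                         seed = 29, max_outer = 2, max_passes = 8)
  s <- attr(cv, "summary")
  expect_equal(s$model, c("LG", "LG+G", "MIX+LG+G"))
  # Direction: fit improves up the ladder on held-out sites.
  expect_lt(s$mean[1], s$mean[3])
  expect_lt(s$mean[2], s$mean[3])
  # The generating family beats the no-gamma homogeneous rung in most
  # folds.
  wide <- reshape(cv, idvar = "fold", timevar = "model",
                  direction = "wide")
  wins <- sum(wide[["test_lnl.MIX+LG+G"]] > wide[["test_lnl.LG"]])
  expect_gte(wins, 2)
  # Determinism of the fold split and scores.
  cv2 <- cross_validation(aln, gen$tree, models = "LG", n_folds = 2,
                          train_sites = 1500, test_sites = 500,
                          seed = 29, max_passes = 8)
  cv3 <- cross_validation(aln, gen$tree, models = "LG", n_folds = 2,
                          train_sites = 1500, test_sites = 500,
                          seed = 29, max_passes = 8)
  expect_equal(cv2$test_lnl, cv3$test_lnl, tolerance = 1e-12)
  expect_error(cross_validation(aln, gen$tree, n_folds = 2,
                                train_sites = 3900, test_sites = 500),
               "exceed")
})
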