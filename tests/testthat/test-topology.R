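test_that("hypothesis trees realize the three arrangements", {
  gen <- make_clade_tree(clade_tree_config(seed = 2))
  hyp <- hypothesis_trees(gen$tree, gen$clade_map, "deuterostome")
  expect_equal(hyp$labels, c("DM", "D1", "D2"))
  le <- c(paste0("L", 1:4), paste0("E", 1:4))
  # D1: Xenambulacraria sister to Protostomia.
  expect_true(lbadiag:::split_in_tree(hyp$trees$D1,
                                      c(le, paste0("X", 1:4))))
  # D2: Chordata sister to Protostomia.
  expect_true(lbadiag:::split_in_tree(hyp$trees$D2,
                                      c(le, paste0("C", 1:4))))
  # Identical tip sets; protostome split everywhere.
  for (lb in hyp$labels) {
    expect_setequal(hyp$trees[[lb]]$tip.label, gen$tree$tip.label)
    expect_true(lbadiag:::split_in_tree(hyp$trees[[lb]], le))
  }
  # Idempotence: re-deriving from the DM output reproduces the topologies.
  hyp2 <- hypothesis_trees(hyp$trees$DM, gen$clade_map, "deuterostome")
  for (lb in hyp$labels)
    expect_equal(ape::dist.topo(ape::unroot(hyp$trees[[lb]]),
                                ape::unroot(hyp2$trees[[lb]])), 0,
                 ignore_attr = TRUE)
  # Protostome focus: P1 groups Lophotrochozoa with the deuterostomes.
  hp <- hypothesis_trees(gen$tree, gen$clade_map, "protostome")
  expect_true(lbadiag:::split_in_tree(
    hp$trees$P1, c(paste0("L", 1:4), paste0("C", 1:4), paste0("X", 1:4))))
})

test_that("ternary scaling is the normalized exponential of lnL gaps", {
  expect_equal(scale_likelihoods(c(-5, -5, -5)), rep(1 / 3, 3))
  w <- scale_likelihoods(c(-10, -1000, -1000))
  expect_gt(w[1], 1 - 1e-12)
  expect_equal(scale_likelihoods(c(-100, -101, -102)),
               c(0.66524, 0.24473, 0.09003), tolerance = 1e-4)
  expect_equal(sum(scale_likelihoods(c(-3, -9, -2))), 1,
               tolerance = 1e-12)
  # Shift invariance and order preservation.
  l <- c(-50.3, -51.2, -49.8)
  expect_equal(scale_likelihoods(l), scale_likelihoods(l + 17),
               tolerance = 1e-12)
  expect_equal(order(scale_likelihoods(l)), order(l))
  expect_error(scale_likelihoods(c(-1, Inf, 0)), "finite")
})

test_that("classification uses a strict two-thirds rule", {
  expect_equal(classify_gene(c(DM = 1, D1 = 0, D2 = 0)), "DM")
  expect_equal(classify_gene(c(DM = 0.5, D1 = 0.3, D2 = 0.2)),
               "unresolved")
  expect_equal(classify_gene(c(DM = 2 / 3, D1 = 1 / 6, D2 = 1 / 6)),
               "unresolved")
  expect_equal(classify_gene(c(DM = 2 / 3 + 1e-9, D1 = 1 / 6,
                               D2 = 1 / 6 - 1e-9)), "DM")
})

test_that("strong-signal genes pick the generating topology", {
  cfg <- clade_tree_config(taxa_per_clan = 2, stem_deut = 0.3,
                           stem_prot = 0.3, seed = 13)
  gen <- make_clade_tree(cfg)
  m <- lg_model(alpha = 1, ncat = 4)
  aln <- simulate_alignment(gen$tree, m, 5000, seed = 13)
  hyp <- hypothesis_trees(gen$tree, gen$clade_map, "deuterostome")
  lnls <- per_gene_topology_lnls(aln, hyp, m)
  expect_equal(names(which.max(lnls)), "DM")
  # Site duplication doubles each lnL and each pairwise difference.
  small <- simulate_alignment(gen$tree, m, 250, seed = 14)
  dup <- aa_alignment(cbind(unclass(small), unclass(small)),
                      name = "dup")
  l1 <- per_gene_topology_lnls(small, hyp, m, tol = 1e-7,
                               max_passes = 80)
  l2 <- per_gene_topology_lnls(dup, hyp, m, tol = 1e-7, max_passes = 80)
  expect_equal(l2, 2 * l1, tolerance = 1e-6)
  # A gene missing an entire clan is filtered.
  noC <- crop_alignment(aln, setdiff(rownames(aln), c("C1", "C2")))
  expect_error(per_gene_topology_lnls(noC, hyp, m), "Chordata")
})

test_that("gene tree inference recovers an easy six-taxon topology", {
  tr <- parse_newick(paste0("((a:0.3,b:0.3):0.15,(c:0.3,d:0.3):0.15,",
                            "(e:0.3,f:0.3):0.15);"))
  m <- lg_model()
  aln <- simulate_alignment(tr, m, 5000, seed = 17)
  est <- infer_gene_tree(aln, m)
  expect_equal(ape::dist.topo(ape::unroot(est), tr), 0,
               ignore_attr = TRUE)
  expect_error(infer_gene_tree(crop_alignment(aln, c("a", "b", "c")), m),
               ">= 4")
})

test_that("four-taxon inference agrees with the exhaustive scan", {
  tr <- parse_newick("((a:0.2,b:0.2):0.1,(c:0.2,d:0.2):0.1);")
  m <- lg_model()
  aln <- simulate_alignment(tr, m, 2000, seed = 18)
  est <- infer_gene_tree(aln, m)
  quartets <- c("((a,b),(c,d));", "((a,c),(b,d));", "((a,d),(b,c));")
  scan <- vapply(quartets, function(q) {
    t0 <- suppressWarnings(parse_newick(q))
    t0$edge.length <- rep(0.1, nrow(t0$edge))
    optimize_branch_lengths(aln, t0, m, tol = 1e-4,
                            max_passes = 40)$lnl
  }, numeric(1))
  best <- suppressWarnings(parse_newick(names(which.max(scan))))
  expect_equal(ape::dist.topo(ape::unroot(est), ape::unroot(best)), 0,
               ignore_attr = TRUE)
  expect_gte(attr(est, "lnl"), max(scan) - 0.1)
})

test_that("monophyly score counts recovered reference splits", {
  tr <- parse_newick("(((a:1,b:1):1,(c:1,d:1):1):1,(e:1,f:1):1);")
  refs <- list(c("a", "b"), c("c", "d"), c("a", "b", "c", "d"),
               c("e", "f"))
  expect_equal(monophyly_score(tr, refs), 1)
  # Break one clade of three testable ones after cropping.
  refs2 <- list(c("a", "c"), c("c", "d"), c("e", "f"))
  expect_equal(monophyly_score(tr, refs2), 2 / 3)
  # Untestable clades leave the denominator.
  expect_equal(monophyly_score(tr, list(c("a", "z"), c("e", "f"))), 1)
  expect_true(is.na(monophyly_score(tr, list(c("a", "z")))))
  # Split-enumeration oracle on random trees.
  for (seed in 1:5) {
    set.seed(seed)
    t1 <- ape::rtree(10)
    sets <- replicate(6, sample(t1$tip.label, sample(2:5, 1)),
                      simplify = FALSE)
    pp <- ape::prop.part(ape::unroot(t1))
    tip_sets <- lapply(pp, function(i) t1$tip.label[i])
    oracle <- mean(vapply(sets, function(s) {
      any(vapply(tip_sets, function(ts)
        setequal(ts, s) || setequal(setdiff(t1$tip.label, ts), s),
        logical(1))) || length(s) == length(t1$tip.label)
    }, logical(1)))
    expect_equal(monophyly_score(t1, sets), oracle)
  }
})

test_that("Welch's t matches the textbook formula", {
  r <- welch_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(r$t, -1.5492, tolerance = 1e-4)
  expect_equal(r$df, 2.9412, tolerance = 1e-4)
  same <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  shifted <- welch_t(c(1, 2, 3) + 10, c(2, 4, 6) + 10)
  expect_equal(shifted$t, r$t, tolerance = 1e-12)
  expect_error(welch_t(1, c(1, 2)), ">= 2")
  expect_error(welch_t(c(2, 2), c(3, 3)), "zero variance")
})

test_that("longer genes resolve more often at equal stems", {
  cfg <- clade_tree_config(taxa_per_clan = 2, stem_deut = 0.05,
                           stem_prot = 0.1, seed = 23)
  gen <- make_clade_tree(cfg)
  m <- lg_model(alpha = 1, ncat = 4)
  hyp <- hypothesis_trees(gen$tree, gen$clade_map, "deuterostome")
  sim_genes <- function(n, len, seed0) {
    lapply(seq_len(n), function(i)
      simulate_alignment(gen$tree, m, len, seed = seed0 + i,
                         name = sprintf("g%d_%d", len, i)))
  }
  genes <- c(sim_genes(55, 150, 4000), sim_genes(55, 1000, 5000))
  tt <- topology_test_genes(genes, hyp, m, max_passes = 10)
  resolved <- tt$category != "unresolved"
  long <- tt$n_sites > 500
  expect_gt(mean(resolved[long]), mean(resolved[!long]))
  wt <- welch_t(tt$n_sites[resolved], tt$n_sites[!resolved])
  expect_lt(wt$p, 0.05)
  expect_gt(wt$t, 0)
  # Counts bookkeeping.
  ts <- triangle_summary(tt)
  expect_equal(sum(ts$counts), nrow(tt))
})

test_that("classification fractions rise with the generating stem", {
  m <- lg_model(alpha = 1, ncat = 4)
  frac_dm <- vapply(c(0.005, 0.05, 0.2), function(stem) {
    cfg <- clade_tree_config(taxa_per_clan = 2, stem_deut = stem,
                             stem_prot = 0.1, seed = 19)
    gen <- make_clade_tree(cfg)
    hyp <- hypothesis_trees(gen$tree, gen$clade_map, "deuterostome")
    genes <- lapply(1:25, function(i)
      simulate_alignment(gen$tree, m, 400,
                         seed = 6000 + round(stem * 1e4) + i,
                         name = paste0("g", i)))
    tt <- topology_test_genes(genes, hyp, m, max_passes = 10)
    mean(tt$category == "DM")
  }, numeric(1))
  expect_true(all(diff(frac_dm) >= 0))
  expect_gt(frac_dm[3], 0.5)
})
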