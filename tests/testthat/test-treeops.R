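test_that("Newick parsing and writing round trip", {
  tr <- parse_newick("((A:1,B:2):0.5,C:3);")
  expect_equal(length(tr$tip.label), 3L)
  expect_equal(stem_of(tr, c("A", "B")), 0.5)
  expect_error(parse_newick("((A:1,B:2:0.5,C:3);"), "unbalanced")
  expect_error(parse_newick("((A:1,A:2):0.5,C:3);"), "duplicate")
  expect_warning(tr0 <- parse_newick("((A,B),C);"), "no branch lengths")
  expect_equal(tr0$edge.length, rep(0, nrow(tr0$edge)))
  # Round-trip identity on random trees.
  for (seed in 1:20) {
    set.seed(seed)
    t1 <- ape::rtree(sample(4:30, 1))
    t2 <- parse_newick(write_newick(t1))
    expect_true(ape::all.equal.phylo(t1, t2, use.edge.length = TRUE,
                                     tolerance = 1e-9))
  }
})

test_that("cropping fuses edges and preserves tip-to-tip distances", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  cr <- crop_tree(tr, c("A", "C", "D"))
  expect_equal(sort(cr$tip.label), c("A", "C", "D"))
  dm <- ape::dist.nodes(cr)[1:3, 1:3]
  rownames(dm) <- colnames(dm) <- cr$tip.label
  expect_equal(dm["A", "C"], 4)
  expect_equal(dm["C", "D"], 2)
  # Distance preservation on random trees.
  for (seed in 1:10) {
    set.seed(seed)
    t1 <- ape::rtree(12)
    keep <- sample(t1$tip.label, 6)
    t2 <- crop_tree(t1, keep)
    d1 <- ape::cophenetic.phylo(t1)[keep, keep]
    d2 <- ape::cophenetic.phylo(t2)[keep, keep]
    expect_equal(d2, d1, tolerance = 1e-9)
  }
  expect_identical(crop_tree(tr, tr$tip.label), tr)
  expect_error(crop_tree(tr, "A"), "fewer than 2")
})

test_that("stem lengths read off the worked tree and match the oracle", {
  tr <- worked_tree()
  cm <- worked_map()
  expect_equal(stem_branch_length(tr, cm, "Protostomia"), 0.4)
  expect_equal(stem_branch_length(tr, cm, "Deuterostomia"), 0.2)
  expect_equal(stem_branch_length(tr, cm, "Chordata"), 0.2 + 0.1)
  # Path additivity: Chordata stem = Deuterostomia stem + inner stem.
  rt <- root_on_outgroup(tr, cm)
  a <- lbadiag:::bilateria_mrca(rt, cm)
  b <- ape::getMRCA(rt, c("C1", "C2"))
  expect_equal(stem_branch_length(tr, cm, "Chordata"),
               dist_oracle(rt, a, b))
})

test_that("non-monophyletic clade raises with intruder names", {
  tr <- parse_newick(
    "(((P1:1,C1:1):0.4,((P2:1,C2:1):0.1,(X1:1,X2:1):0.1):0.2):0.3,O1:2);")
  cm <- worked_map()
  expect_error(stem_branch_length(tr, cm, "Deuterostomia"),
               "not monophyletic")
})

test_that("collapse produces the expected polytomy and edge count", {
  tr <- worked_tree()
  cm <- worked_map()
  col <- collapse_branch(tr, cm, "Deuterostomia")
  n_internal <- function(t) sum(t$edge[, 2] > length(t$tip.label))
  expect_equal(n_internal(col), n_internal(root_on_outgroup(tr, cm)) - 1L)
  # Bilaterian node is now a trifurcation: (P1,P2), (C1,C2), (X1,X2).
  cmrca <- ape::getMRCA(col, c("C1", "C2"))
  xmrca <- ape::getMRCA(col, c("X1", "X2"))
  pmrca <- ape::getMRCA(col, c("P1", "P2"))
  bil <- lbadiag:::bilateria_mrca(col, cm)
  expect_equal(col$edge[col$edge[, 2] == cmrca, 1], bil)
  expect_equal(col$edge[col$edge[, 2] == xmrca, 1], bil)
  expect_equal(col$edge[col$edge[, 2] == pmrca, 1], bil)
  expect_equal(stem_branch_length(col, cm, "Deuterostomia"), 0)
  # Collapsing a zero-length stem preserves all tip-to-tip distances.
  tr2 <- parse_newick(
    "(((P1:1,P2:1):0.4,((C1:1,C2:1):0.1,(X1:1,X2:1):0.1):0):0.3,O1:2);")
  col2 <- collapse_branch(tr2, cm, "Deuterostomia")
  expect_equal(ape::cophenetic.phylo(col2)[tr2$tip.label, tr2$tip.label],
               ape::cophenetic.phylo(tr2)[tr2$tip.label, tr2$tip.label],
               tolerance = 1e-9)
  expect_error(collapse_branch(col, cm, "Deuterostomia"),
               "not monophyletic|no stem")
})

test_that("root-to-tip depths match the distance-matrix oracle", {
  tr <- worked_tree()
  cm <- worked_map()
  d <- root_to_tip_lengths(tr, cm)
  rt <- root_on_outgroup(tr, cm)
  bil <- lbadiag:::bilateria_mrca(rt, cm)
  for (tx in names(d)) {
    expect_equal(d[[tx]],
                 dist_oracle(rt, bil, match(tx, rt$tip.label)))
  }
  expect_equal(d[["C1"]], 0.2 + 0.1 + 1)
  # Random trees against the oracle.
  for (seed in 1:5) {
    cfg <- clade_tree_config(seed = seed)
    m <- make_clade_tree(cfg)
    dd <- root_to_tip_lengths(m$tree, m$clade_map)
    rt2 <- root_on_outgroup(m$tree, m$clade_map)
    bil2 <- lbadiag:::bilateria_mrca(rt2, m$clade_map)
    for (tx in sample(names(dd), 4))
      expect_equal(dd[[tx]],
                   dist_oracle(rt2, bil2, match(tx, rt2$tip.label)))
  }
})

test_that("clade map validates disjointness and derives unions", {
  expect_error(clade_map("O1", "L1", c("L1", "E1"), "C1", "X1"),
               "more than one clan")
  cm <- worked_map()
  expect_setequal(clan_taxa(cm, "Protostomia"), c("P1", "P2"))
  expect_setequal(clan_taxa(cm, "Deuterostomia"), c("C1", "C2", "X1",
                                                    "X2"))
  expect_setequal(clan_taxa(cm, "Bilateria"),
                  c("P1", "P2", "C1", "C2", "X1", "X2"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clade_map(cm, path)
  cm2 <- read_clade_map(path)
  expect_equal(unclass(cm2), unclass(cm))
})
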