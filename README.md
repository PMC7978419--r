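# lbadiag

Branch-support statistics and long-branch-attraction (LBA) diagnostics
for contested internal branches of phylogenomic trees, built around the
deuterostome-monophyly problem: is the branch uniting Chordata and
Xenambulacraria real, or an artifact of systematic error?

The package is aimed at molecular phylogeneticists who want to
interrogate a weakly supported clade against a well-supported control
clade with likelihood machinery they can audit end to end. Everything
runs on synthetic, clade-structured data generated in-package, so every
analysis is reproducible without downloads.

## What it computes

For a bilaterian-style system with five clans (Outgroup,
Lophotrochozoa, Ecdysozoa, Chordata, Xenambulacraria), with
Protostomia = L+E and Deuterostomia = C+X:

* **Stem branch lengths** — the path from the Bilateria common ancestor
  to a clade's common ancestor after outgroup rooting, in expected
  substitutions/site (`stem_branch_length`, `clade_depth_summary`,
  `dataset_rate`).
* **The ΔlnL collapse statistic** — the loss in optimized log-likelihood
  when a focal stem is pinned to zero (a polytomy, by reversibility) and
  every other branch is re-optimized:
  ΔlnL = lnL(resolved) − lnL(collapsed) ≥ 0
  (`delta_lnl_collapse`, `per_gene_branch_table`).
* **Per-gene three-topology tests** — each gene's optimized lnL under
  the three resolutions of the contested trichotomy (DM, D1, D2 — or
  PM, P1, P2 for the protostome control), scaled to ternary likelihood
  weights `w_i ∝ exp(lnL_i − max lnL)` and classified by a strict > 2/3
  rule (`hypothesis_trees`, `per_gene_topology_lnls`,
  `scale_likelihoods`, `classify_gene`, `triangle_summary`), plus
  gene-quality covariates (`monophyly_score`, `infer_gene_tree`,
  `welch_t`).
* **Topology-recovery experiments** — simulate under DM/D1/D2 with a
  site-heterogeneous profile-mixture model (LG exchangeabilities,
  discrete-gamma rates, Dirichlet profile libraries), then reinfer each
  replicate by constrained choice among the three resolutions under:
  the matched mixture (Het), site-homogeneous LG+F+G (Hom), and Hom
  after removing the longest- (HomNL) or shortest-branched (HomNS)
  protostome and outgroup taxa (`run_lba_experiment`,
  `taxon_removal_sets`, `select_topology`); plus a site-subsampling
  cross-validation ladder LG → LG+G → MIX+LG+G (`cross_validation`,
  `fit_model`).

The likelihood core (Felsenstein pruning, profile mixtures,
coordinate-ascent branch-length optimization, sequence simulation) is
implemented in C++ (RcppArmadillo) with per-node rescaling and
eigendecomposition-based edge scoring.

## Worked example

```r
library(lbadiag)

# A synthetic study system: 5 clans, short deuterostome stem (0.01),
# longer protostome stem (0.05), long outgroup/protostome branches.
gen      <- make_clade_tree(clade_tree_config(seed = 1))
profiles <- make_profile_library(K = 10, concentration = 0.2, seed = 42)
model    <- subst_model(profiles, alpha = 0.7, ncat = 4)
aln      <- simulate_alignment(gen$tree, model, n_sites = 2000, seed = 101)

# Stem lengths and collapse support, scored under site-homogeneous
# LG+F+G (as the empirical analyses do).
hom <- lg_model(empirical_frequencies(aln), alpha = 0.7, ncat = 4)
for (clade in c("Protostomia", "Deuterostomia")) {
  d <- delta_lnl_collapse(aln, gen$tree, gen$clade_map, clade, hom,
                          max_passes = 40)
  cat(sprintf("%-14s stem = %6.4f   delta-lnL(collapse) = %7.2f\n",
              clade, d$stem_length, d$delta_lnl))
}

# Three-topology test of the contested trichotomy.
hyp  <- hypothesis_trees(gen$tree, gen$clade_map, focus = "deuterostome")
lnls <- per_gene_topology_lnls(aln, hyp, hom, max_passes = 40)
w    <- scale_likelihoods(lnls)
cat("ternary weights:", sprintf("%s=%.3f", names(lnls), w),
    "->", classify_gene(setNames(w, names(lnls))), "\n")
```

Output:

```
Protostomia    stem = 0.0316   delta-lnL(collapse) =   24.44
Deuterostomia  stem = 0.0202   delta-lnL(collapse) =   12.83
ternary weights: DM=0.989 D1=0.011 D2=0.000 -> DM
```

Both readings favor the control clade: the protostome stem is longer
and collapsing it costs about twice as many log-likelihood units as
collapsing the deuterostome stem. Note also a signature of model
violation: the data were generated with stems 0.05 (protostome) and
0.01 (deuterostome), but the homogeneous fit *deflates* the protostome
stem and *inflates* the contested deuterostome stem — the same
direction of bias that makes poorly fitting models overstate support
for the contested clade.

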