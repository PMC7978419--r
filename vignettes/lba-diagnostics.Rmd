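---
title: "Diagnosing support for a contested internal branch"
author: "lbadiag"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing support for a contested internal branch}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Animal phylogenomics treats Bilateria as two sister superclades:
Protostomia (Lophotrochozoa + Ecdysozoa) and Deuterostomia (Chordata +
Xenambulacraria). Protostome monophyly is robust across datasets;
deuterostome monophyly is not. The branch between the bilaterian common
ancestor and the putative deuterostome ancestor — the *deuterostome stem*
— is at best very short, and the conditions known to produce systematic
error in tree reconstruction (site-heterogeneous amino-acid preferences
modelled homogeneously, strong among-lineage rate inequality, short
internal branches) all coincide with datasets that support it.

`lbadiag` implements the statistics and simulation machinery needed to
interrogate such a contested branch against a well-supported control
branch:

* **stem lengths** (`stem_branch_length`): the path length from the
  Bilateria MRCA to a clade's MRCA after outgroup rooting, in expected
  substitutions per site;
* **the collapse statistic** (`delta_lnl_collapse`): the drop in
  optimized log-likelihood when the focal stem is pinned at zero
  (likelihood-equivalent to a polytomy under a reversible model) and all
  other branch lengths are re-optimized from the same starting point;
* **per-gene three-topology tests** (`per_gene_topology_lnls`,
  `scale_likelihoods`, `classify_gene`): each gene's likelihood under the
  three resolutions of the contested trichotomy, scaled to ternary
  likelihood weights $w_i = e^{\ell_i - \max_j \ell_j} / \sum_k
  e^{\ell_k - \max_j \ell_j}$ and classified by a strict $>2/3$ rule;
* **a topology-recovery experiment** (`run_lba_experiment`): simulate
  under each candidate arrangement with a site-heterogeneous model, then
  reinfer under matched and deliberately violated models, with and
  without the longest/shortest-branched protostome and outgroup taxa, to
  ask which arrangements can gain *artifactual* support.

## Substitution model

The engine computes amino-acid likelihoods by Felsenstein pruning under a
general reversible model built from LG exchangeabilities $s_{ij}$ and a
frequency profile $\pi$: $Q_{ij} = s_{ij}\pi_j$, calibrated so that
$-\sum_i \pi_i Q_{ii} = 1$ (branch lengths are expected substitutions per
site under every mixture component). Site heterogeneity is modelled as a
finite mixture of $K$ profiles with weights $w_k$; the site likelihood is
the weighted average of per-profile likelihoods. Rate variation uses
Yang's equal-probability discrete gamma (`discretize_gamma`; $K=4$
categories by default, category means renormalized to average exactly 1).
This finite-mixture maximum-likelihood treatment stands in for Bayesian
infinite-mixture (CAT-type) modelling: it expresses the same idea —
site-specific amino-acid preferences — while remaining deterministic and
desk-scale. A single-profile model with observed "+F" frequencies
(pseudocount 1 per residue, not iterated) is the site-homogeneous rung.

Numerical choices: profiles are floored at $10^{-6}$ and renormalized
before the symmetric eigendecomposition $P(t) = V e^{\Lambda t} V^{-1}$;
transition probabilities are clamped at zero against roundoff; partial
likelihoods are rescaled per node and site with log-offset bookkeeping;
gaps and `X` contribute all-ones partials (standard missing-data
treatment); site patterns are compressed with multiplicity weights.

## Branch-length optimization

`optimize_branch_lengths` performs coordinate ascent at fixed topology:
each pass refreshes the conditional (subtree) partials in postorder, then
sweeps the edges in preorder, maintaining outside partials so that each
1-D problem is exact for the current state, and optimizes each free edge
by bounded Brent search (bounds $[10^{-8}, 20]$; flat likelihood regions
resolve toward the lower bound). In the eigenbasis a candidate length is
scored with a single $S \times 20$ matrix–vector product per mixture
component, so the Brent iterations are cheap relative to the flank
computation. Passes repeat until the log-likelihood improves by less
than `tol` (default $10^{-4}$ nats); the best state seen is returned, so
the reported likelihood never falls below the starting value, and
non-convergence sets a flag (with a warning) rather than failing. Rooted
binary input is unrooted internally — the two root branches of a
reversible model are confounded — and the merged length is shared back
proportionally. Edges can be pinned (`fixed_edges`), which is how the
collapse statistic holds a stem at zero while everything else is free.

`fit_model` interleaves these passes with bounded gamma-shape search
($\alpha \in [0.05, 20]$, log scale) and, for the mixture rung, EM
updates of the mixture weights (per-profile site likelihoods do not
depend on the weights, so each EM solves its subproblem to convergence
cheaply). Parameter updates are only accepted when they improve the
joint likelihood, making the outer iteration monotone.

## The synthetic study system

`make_clade_tree` builds a five-clan tree (Outgroup, Lophotrochozoa,
Ecdysozoa, Chordata, Xenambulacraria) around the contested trichotomy,
with three generating arrangements: `DM` (monophyletic deuterostomes),
`D1` (Xenambulacraria sister to Protostomia) and `D2` (Chordata sister to
Protostomia). Defaults encode the empirical regime the analyses probe:

* a very short deuterostome-side stem (`stem_deut = 0.01`) against a
  longer protostome stem (`stem_prot = 0.05`);
* long outgroup and protostome lineages versus short chordate and
  xenambulacrarian ones (mean within-clan depths $0.9 \times$ multipliers
  1.2 / 1.0 / 1.0 / 0.35 / 0.35);
* strong among-taxon rate inequality *within* clans (`depth_spread = 0.5`
  on the log scale, i.e. a geometric spread of roughly $1.6\times$ per
  standard deviation), applied through the terminal branches. This is
  essential structure, not decoration: the longest/shortest taxon-removal
  experiments are only meaningful when clans contain genuinely long- and
  short-branched members, as real datasets do;
* within-clan topologies are random (coalescent-like shapes from random
  trees): only clan-level structure enters any downstream statistic;
* structural lengths chosen once as realistic: clan stems 0.15, root-side
  stems 0.3.

Site heterogeneity comes from `make_profile_library`: $K$ profiles drawn
from a symmetric Dirichlet with concentration 0.2, giving sparse,
CAT-like profiles dominated by a few residues. `make_geneset` adds
per-gene lognormal lengths (median 300, floor 50), lognormal rate
multipliers, and uniform taxon occupancy (0.8) that never empties a clan
when a clan map is supplied.

What the generator does **not** emulate: real lineage-specific
amino-acid composition, structured (non-uniform) missingness, indels and
alignment error, and among-gene model heterogeneity beyond a scalar
rate. Passing tests therefore demonstrate correctness of the machinery
and reproduction of the *mechanism* under controlled conditions, not
claims about any particular empirical dataset.

## The recovery experiment

`run_lba_experiment` simulates `n_replicates` alignments per generating
topology (replicate $r$ of topology $T$ uses seed
`base_seed + seed_offsets[T] + r`) and reinfers each replicate as a
constrained choice among the three clan-level resolutions
(`select_topology`): branch lengths are optimized on each hypothesis
tree and the maximum-likelihood label wins; ties within $10^{-6}$ nats
resolve in the fixed order DM, D1, D2 and are flagged. Constraining the
choice to the three resolutions (with within-clan topology held at the
truth) reflects the actual question — which resolution wins — and keeps
the experiment deterministic and desk-scale; it stands in for the full
tree searches a heavier pipeline would run.

Conditions:

* **Het** — the matched site-heterogeneous model: the generating profile
  library, weights and gamma shape. (EM re-fitting of the weights per
  hypothesis is available via `het_refit_weights = TRUE`; the default
  scores with the generating weights, which is both the cleaner
  "matched model" reading and lower-variance.)
* **Hom** — the model-violating site-homogeneous LG+F+G: observed
  frequencies and a gamma shape freshly estimated from each replicate.
* **HomNL / HomNS** — Hom after removing the `removal_k` longest- or
  shortest-branched protostome and outgroup taxa
  (`taxon_removal_sets`; default `removal_k` is half those taxa, ranked
  by distance from the bilaterian ancestor, ties by name, never removing
  a clan's last member). Frequencies and shape are re-estimated on the
  cropped data.

The mechanism under study: with deuterostomes actually paraphyletic, a
homogeneous model plus long protostome/outgroup branches pulls the
outgroup toward the long protostomes, stranding the short chordates and
xenambulacrarians together — spurious "deuterostomes". Removing the long
branches suppresses the artifact; removing the short branches enhances
it. A companion signature (asserted as a property test): on
heterogeneous data the homogeneous fit *inflates* the contested stem and
deflates the protostome stem, so per-gene stem comparisons are scored
under the matched model when the question is the generating geometry,
and under the homogeneous model when the question is the bias itself.

`cross_validation` supplies the model-fit ladder: disjoint train/test
site subsamples, each model fitted on the training sites and scored on
the held-out sites at the fitted parameters.

## Problem sizes

The package's own acceptance experiments use 20 replicates of 2,000
sites per generating topology on the default 20-taxon tree — sizes
chosen so the full suite runs on a single desk CPU while keeping roughly
20 expected substitutions on the contested stem per replicate. Unit and
property tests use 4–20 taxa and $10^2$–$5\times10^4$ sites, with exact
oracles (matrix-exponential enumeration, quadrature, grid search,
split enumeration, textbook formulas) on the small end and statistical
tolerances (binomial standard errors, parameter-recovery bands) on the
large end.

## Known limitations

* The likelihood engine is a fixed-topology tool; `infer_gene_tree`'s
  NJ + NNI hill climb is adequate for per-gene monophyly scores, not a
  general tree-search replacement.
* The finite profile mixture fixes its profile library; only weights,
  shape and branch lengths are estimated. Site-specific posterior-mean
  frequency approximations are out of scope.
* At 2,000 sites the contested-stem signal is weak by design; individual
  replicates of the matched-model condition can be genuinely ambiguous
  (near-tied likelihoods). The experiment reports tallies and flags tie
  decisions rather than hiding them.
* Gaps are treated as missing data; no indel model.
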