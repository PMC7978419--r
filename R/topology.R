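# Per-gene three-topology likelihood machinery: hypothesis tree
# construction, likelihood scoring, ternary scaling and classification,
# gene-tree inference, monophyly scores, and informativeness contrasts.

#' Build the three competing arrangements of the focal clans
#'
#' From a reference tree in which the four focal clans are each
#' monophyletic, constructs the three resolutions of the contested
#' trichotomy, preserving all within-clan subtrees, clan stem lengths, and
#' the outgroup attachment. Backbone branches that exist in the reference
#' keep their lengths; rearranged backbone branches are initialized at
#' 0.05.
#'
#' For `focus = "deuterostome"` the hypotheses are `DM` (monophyletic
#' Deuterostomia, `((L,E),(C,X))`), `D1` (Xenambulacraria sister to
#' Protostomia, `(C,(X,(L,E)))`) and `D2` (Chordata sister to Protostomia,
#' `(X,(C,(L,E)))`). For `focus = "protostome"`: `PM`, `P1` (Lophotrochozoa
#' sister to Deuterostomia) and `P2` (Ecdysozoa sister to Deuterostomia).
#'
#' @param reference_tree A `phylo` tree containing outgroup taxa.
#' @param cm A [clade_map()].
#' @param focus `"deuterostome"` or `"protostome"`.
#' @return A `hypothesis_set`: list of three `phylo` trees (named by
#'   label), plus `labels`, `focus` and the clan map.
#' @export
hypothesis_trees <- function(reference_tree, cm,
                             focus = c("deuterostome", "protostome")) {
  focus <- match.arg(focus)
  tree <- root_on_outgroup(reference_tree, cm)
  clans <- c("Lophotrochozoa", "Ecdysozoa", "Chordata", "Xenambulacraria")
  for (cl in clans) {
    tx <- clan_taxa(cm, cl, tree)
    if (!length(tx)) stop_invalid("clan ", cl, " has no taxa in tree")
    if (!clade_is_monophyletic(tree, tx))
      stop_invalid("clan ", cl, " is not monophyletic in the reference")
  }
  ch <- lapply(c(Outgroup = "Outgroup", setNames(clans, clans)),
               function(cl) clan_chunk(tree, clan_taxa(cm, cl, tree)))
  # Root-side attachment lengths.
  root <- length(tree$tip.label) + 1L
  redges <- which(tree$edge[, 1L] == root)
  og <- clan_taxa(cm, "Outgroup", tree)
  desc <- descendant_tips(tree)
  og_side <- vapply(redges, function(e) {
    all(tree$tip.label[desc[[tree$edge[e, 2L]]]] %in% og)
  }, logical(1L))
  og_len <- sum(tree$edge.length[redges[og_side]])
  bil_len <- sum(tree$edge.length[redges[!og_side]])
  blen <- function(...) {
    taxa <- unlist(lapply(c(...), clan_taxa, cm = cm, tree = tree))
    if (split_in_tree(tree, taxa))
      tree$edge.length[edge_for_split(tree, taxa)]
    else 0.05
  }
  at <- function(chunk) sprintf("%s:%.10g", chunk$nwk, chunk$stem)
  L <- at(ch$Lophotrochozoa); E <- at(ch$Ecdysozoa)
  C <- at(ch$Chordata); X <- at(ch$Xenambulacraria)
  if (focus == "deuterostome") {
    labels <- c("DM", "D1", "D2")
    prot <- sprintf("(%s,%s):%.10g", L, E, blen("Lophotrochozoa",
                                                "Ecdysozoa"))
    bodies <- c(
      DM = sprintf("(%s,(%s,%s):%.10g)", prot, C, X,
                   blen("Chordata", "Xenambulacraria")),
      D1 = sprintf("(%s,(%s,%s):%.10g)", C, X, prot,
                   blen("Xenambulacraria", "Lophotrochozoa", "Ecdysozoa")),
      D2 = sprintf("(%s,(%s,%s):%.10g)", X, C, prot,
                   blen("Chordata", "Lophotrochozoa", "Ecdysozoa")))
  } else {
    labels <- c("PM", "P1", "P2")
    deut <- sprintf("(%s,%s):%.10g", C, X, blen("Chordata",
                                                "Xenambulacraria"))
    bodies <- c(
      PM = sprintf("((%s,%s):%.10g,%s)", L, E,
                   blen("Lophotrochozoa", "Ecdysozoa"), deut),
      P1 = sprintf("(%s,(%s,%s):%.10g)", E, L, deut,
                   blen("Lophotrochozoa", "Chordata", "Xenambulacraria")),
      P2 = sprintf("(%s,(%s,%s):%.10g)", L, E, deut,
                   blen("Ecdysozoa", "Chordata", "Xenambulacraria")))
  }
  trees <- lapply(bodies, function(b) {
    parse_newick(sprintf("(%s:%.10g,%s:%.10g);", ch$Outgroup$nwk, og_len,
                         b, bil_len))
  })
  names(trees) <- labels
  structure(list(trees = trees, labels = labels, focus = focus,
                 clade_map = cm), class = "hypothesis_set")
}

# Newick chunk (no trailing ';') and stem length of a clan's subtree.
clan_chunk <- function(tree, taxa) {
  if (length(taxa) == 1L) {
    tip <- match(taxa, tree$tip.label)
    e <- which(tree$edge[, 2L] == tip)
    return(list(nwk = taxa, stem = tree$edge.length[e]))
  }
  node <- ape::getMRCA(tree, taxa)
  sub <- ape::extract.clade(tree, node)
  e <- which(tree$edge[, 2L] == node)
  list(nwk = sub(";$", "", write_newick(sub)),
       stem = if (length(e)) tree$edge.length[e] else 0)
}

#' @export
print.hypothesis_set <- function(x, ...) {
  cat(sprintf("hypothesis_set (%s focus): %s\n", x$focus,
              paste(x$labels, collapse = ", ")))
  invisible(x)
}

# NULL if the gene passes the clan-representation filter, else the reason.
gene_topology_filter <- function(gene, cm) {
  tx <- rownames(gene)
  for (cl in c("Lophotrochozoa", "Ecdysozoa", "Chordata",
               "Xenambulacraria", "Outgroup"))
    if (!length(intersect(tx, cm[[cl]])))
      return(paste0("no ", cl, " taxon"))
  NULL
}

#' Per-gene log-likelihoods of the three hypotheses
#'
#' Each hypothesis tree is cropped to the gene's taxa and its branch
#' lengths optimized independently; the three optimized log-likelihoods are
#' returned in label order. Genes lacking a taxon in any focal clan or the
#' outgroup raise an error (drivers skip and log them).
#'
#' @param gene An [aa_alignment()].
#' @param hypotheses A [hypothesis_trees()] result.
#' @param model A [subst_model()].
#' @param tol,max_passes Optimizer settings.
#' @return Named numeric vector of three log-likelihoods.
#' @export
per_gene_topology_lnls <- function(gene, hypotheses, model, tol = 1e-3,
                                   max_passes = 15L) {
  reason <- gene_topology_filter(gene, hypotheses$clade_map)
  if (!is.null(reason)) stop_invalid("gene filtered: ", reason)
  vapply(hypotheses$labels, function(lb) {
    tr <- crop_tree(hypotheses$trees[[lb]], rownames(gene))
    optimize_branch_lengths(gene, tr, model, tol = tol,
                            max_passes = max_passes)$lnl
  }, numeric(1L))
}

#' Ternary likelihood weights
#'
#' Scales three log-likelihoods to the unit simplex as normalized
#' exponentials of their differences (relative likelihood weights), the
#' coordinates used for ternary support plots. Invariant to adding a
#' constant to all three.
#'
#' @param lnls Numeric vector of three finite log-likelihoods.
#' @return Numeric vector of three weights summing to 1.
#' @export
scale_likelihoods <- function(lnls) {
  if (length(lnls) != 3L || !all(is.finite(lnls)))
    stop_invalid("lnls must be three finite values")
  w <- exp(lnls - max(lnls))
  w / sum(w)
}

#' Classify a gene from its ternary weights
#'
#' A gene supports the topology whose scaled likelihood strictly exceeds
#' `threshold` (default 2/3); otherwise it is `"unresolved"` (the gray
#' central band of the ternary plot). The boundary itself is unresolved.
#'
#' @param point Weights from [scale_likelihoods()] (named by label).
#' @param threshold Support cutoff.
#' @return The winning label or `"unresolved"`.
#' @export
classify_gene <- function(point, threshold = 2 / 3) {
  hit <- which(point > threshold)
  if (length(hit) == 1L)
    (names(point) %||% paste0("topology", 1:3))[hit]
  else "unresolved"
}

#' Score and classify a gene set against three hypotheses
#'
#' Driver over [per_gene_topology_lnls()]: returns a per-gene table of
#' log-likelihoods, ternary weights and category; filtered genes are logged
#' in `attr(, "skipped")`.
#'
#' @param genes List of [aa_alignment()] objects.
#' @inheritParams per_gene_topology_lnls
#' @param threshold Support cutoff for [classify_gene()].
#' @return Data frame with columns `gene`, `n_sites`, `lnl_*`, `w_*`,
#'   `category`.
#' @export
topology_test_genes <- function(genes, hypotheses, model, threshold = 2 / 3,
                                tol = 1e-3, max_passes = 15L) {
  lb <- hypotheses$labels
  rows <- list()
  skipped <- list()
  for (g in genes) {
    nm <- attr(g, "name") %||% "gene"
    reason <- gene_topology_filter(g, hypotheses$clade_map)
    if (!is.null(reason)) {
      skipped[[nm]] <- reason
      next
    }
    lnls <- per_gene_topology_lnls(g, hypotheses, model, tol = tol,
                                   max_passes = max_passes)
    w <- scale_likelihoods(lnls)
    row <- data.frame(gene = nm, n_sites = ncol(g))
    row[paste0("lnl_", lb)] <- as.list(lnls)
    row[paste0("w_", lb)] <- as.list(w)
    row$category <- classify_gene(setNames(w, lb), threshold)
    rows[[nm]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(out)) rownames(out) <- NULL
  attr(out, "skipped") <- unlist(skipped)
  out
}

#' Summarize a classified gene table
#'
#' @param df Output of [topology_test_genes()].
#' @return List with `counts` (per category, summing to the number of
#'   classified genes) and `coordinates` (the ternary weight table).
#' @export
triangle_summary <- function(df) {
  lb <- sub("^w_", "", grep("^w_", colnames(df), value = TRUE))
  counts <- setNames(integer(length(lb) + 1L), c(lb, "unresolved"))
  tab <- table(df$category)
  counts[names(tab)] <- as.integer(tab)
  list(counts = counts,
       coordinates = df[, c("gene", paste0("w_", lb), "category")])
}

#' Welch's two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value (delegated to [stats::t.test()]).
#'
#' @param a,b Numeric vectors (each >= 2 values; at least one group with
#'   nonzero variance).
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop_invalid("each group needs >= 2 observations")
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop_invalid("both groups have zero variance")
  res <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Maximum-likelihood gene tree by NJ + NNI hill climbing
#'
#' Neighbor joining on pairwise maximum-likelihood distances under the
#' model, followed by nearest-neighbor-interchange hill climbing with full
#' branch-length optimization of each candidate, until no rearrangement
#' improves the log-likelihood. Deterministic given its input.
#'
#' @param aln An [aa_alignment()] with >= 4 taxa.
#' @param model A [subst_model()].
#' @param tol,max_passes Optimizer settings per candidate.
#' @return The best `phylo` tree found, with attribute `lnl`.
#' @export
infer_gene_tree <- function(aln, model, tol = 1e-2, max_passes = 10L) {
  if (nrow(aln) < 4L) stop_invalid("need >= 4 taxa for tree inference")
  D <- ml_distance_matrix(aln, model)
  tr <- ape::unroot(ape::nj(D))
  tr$edge.length <- pmax(tr$edge.length, 1e-4)
  cur <- optimize_branch_lengths(aln, tr, model, tol = tol,
                                 max_passes = max_passes)
  repeat {
    base <- cur$tree
    attr(base, "order") <- NULL
    base <- ape::reorder.phylo(base, "cladewise")
    cands <- phangorn::nni(base)
    best <- NULL
    for (i in seq_along(cands)) {
      cand <- cands[[i]]   # multiPhylo: `[[` re-attaches shared tip labels
      if (is.null(cand$edge.length))
        cand$edge.length <- rep(0.1, nrow(cand$edge))
      fit <- optimize_branch_lengths(aln, cand, model, tol = tol,
                                     max_passes = max_passes)
      if (is.null(best) || fit$lnl > best$lnl) best <- fit
    }
    if (!is.null(best) && best$lnl > cur$lnl + 1e-3) cur <- best
    else break
  }
  out <- cur$tree
  attr(out, "lnl") <- cur$lnl
  out
}

#' Pairwise maximum-likelihood distances
#'
#' For each taxon pair, the branch length maximizing the two-sequence
#' likelihood under the model (sites with a gap or `X` in either sequence
#' are ignored).
#'
#' @inheritParams infer_gene_tree
#' @return A symmetric distance matrix.
#' @export
ml_distance_matrix <- function(aln, model) {
  prep <- prepare_model(model)
  codes <- aln_codes(aln)
  n <- nrow(aln)
  K <- length(prep$V); C <- length(prep$rates)
  mix_P <- function(t) {
    M <- matrix(0, 20L, 20L)
    for (k in seq_len(K)) for (c in seq_len(C)) {
      P <- prep$V[[k]] %*% (exp(prep$lam[[k]] * t * prep$rates[c]) *
                              prep$Vi[[k]])
      P[P < 0] <- 0
      M <- M + (prep$wk[k] / C) * (prep$pimat[, k] * P)
    }
    M
  }
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- codes[i, ] > 0L & codes[j, ] > 0L
    if (!any(ok)) {
      D[i, j] <- D[j, i] <- 5
      next
    }
    N <- table(factor(codes[i, ok], levels = 1:20),
               factor(codes[j, ok], levels = 1:20))
    obj <- function(t) {
      M <- mix_P(t)
      M[M < 1e-300] <- 1e-300
      sum(N * log(M))
    }
    opt <- optimize(obj, c(1e-6, 20), maximum = TRUE, tol = 1e-6)
    D[i, j] <- D[j, i] <- opt$maximum
  }
  D
}

#' Monophyly score of a tree against reference clades
#'
#' The fraction of reference clades that are recovered as unrooted splits
#' in the tree, among clades "testable" there (at least two member taxa
#' present). Clades covering every tip are trivially recovered; a tree with
#' no testable clade scores `NA`.
#'
#' @param tree A `phylo` tree.
#' @param reference_clades List of character vectors of taxon names.
#' @return A value in `[0, 1]`, or `NA` if no clade is testable.
#' @export
monophyly_score <- function(tree, reference_clades) {
  tips <- tree$tip.label
  testable <- 0L
  recovered <- 0L
  for (cl in reference_clades) {
    pres <- intersect(tips, cl)
    if (length(pres) < 2L) next
    testable <- testable + 1L
    if (length(pres) == length(tips)) {
      recovered <- recovered + 1L
      next
    }
    if (split_in_tree(tree, pres)) recovered <- recovered + 1L
  }
  if (testable == 0L) return(NA_real_)
  recovered / testable
}
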