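# Stem-length and likelihood-collapse statistics for the focal clades, on
# concatenated and per-gene data; clade depth summaries; dataset rate.

#' Likelihood cost of collapsing a clade's stem branch
#'
#' The difference in optimized log-likelihood between the fully resolved
#' topology and the same topology with the focal stem pinned at length zero
#' (likelihood-equivalent to a true polytomy under a reversible model), all
#' other branch lengths re-optimized from the same starting lengths.
#'
#' @inheritParams optimize_branch_lengths
#' @param cm A [clade_map()].
#' @param clade `"Protostomia"` or `"Deuterostomia"` (any [clan_taxa()]
#'   name).
#' @return List with `delta_lnl` (>= 0 up to optimizer tolerance),
#'   `stem_length` (resolved fit), `lnl_resolved`, `lnl_collapsed`.
#' @export
delta_lnl_collapse <- function(aln, topology, cm, clade, model, tol = 1e-4,
                               max_passes = 30L) {
  tree <- root_on_outgroup(topology, cm)
  taxa <- clan_taxa(cm, clade, tree)
  if (!clade_is_monophyletic(tree, taxa))
    stop_invalid("clade '", clade, "' is not monophyletic in topology")
  a <- bilateria_mrca(tree, cm)
  b <- ape::getMRCA(tree, taxa)
  if (a == b)
    stop_invalid("clade MRCA coincides with Bilateria MRCA; no stem branch")
  np <- ape::nodepath(tree, a, b)
  if (length(np) != 2L)
    stop_invalid("stem spans more than one branch")
  e <- which(tree$edge[, 1L] == a & tree$edge[, 2L] == b)
  res <- optimize_branch_lengths(aln, tree, model, tol = tol,
                                 max_passes = max_passes)
  ctree <- tree
  ctree$edge.length[e] <- 0
  col <- optimize_branch_lengths(aln, ctree, model, fixed_edges = e,
                                 tol = tol, max_passes = max_passes)
  list(delta_lnl = res$lnl - col$lnl,
       stem_length = res$tree$edge.length[e],
       lnl_resolved = res$lnl, lnl_collapsed = col$lnl)
}

#' Per-gene stem lengths and collapse statistics
#'
#' For each gene: the reference topology is cropped to the gene's taxa,
#' branch lengths are optimized, and the stem length and collapse delta-lnL
#' are recorded for both Protostomia and Deuterostomia. Genes lacking two
#' taxa in either clan union or an outgroup taxon are skipped (reasons in
#' `attr(, "skipped")`).
#'
#' @param genes List of [aa_alignment()] objects.
#' @param reference_tree A `phylo` reference topology covering all taxa.
#' @param cm A [clade_map()].
#' @param model A [subst_model()].
#' @param tol,max_passes Optimizer settings per gene.
#' @return A data frame with columns `unit`, `clade`, `stem_length`,
#'   `delta_lnl` (two rows per analysed gene).
#' @export
per_gene_branch_table <- function(genes, reference_tree, cm, model,
                                  tol = 1e-3, max_passes = 15L) {
  rows <- list()
  skipped <- list()
  for (g in genes) {
    nm <- attr(g, "name") %||% "gene"
    reason <- branch_gene_filter(g, cm)
    if (!is.null(reason)) {
      skipped[[nm]] <- reason
      next
    }
    tr <- crop_tree(reference_tree, rownames(g))
    rec <- lapply(c("Protostomia", "Deuterostomia"), function(cl) {
      d <- delta_lnl_collapse(g, tr, cm, cl, model, tol = tol,
                              max_passes = max_passes)
      data.frame(unit = nm, clade = cl, stem_length = d$stem_length,
                 delta_lnl = d$delta_lnl)
    })
    rows[[nm]] <- do.call(rbind, rec)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(unit = character(), clade = character(),
               stem_length = numeric(), delta_lnl = numeric())
  rownames(out) <- NULL
  attr(out, "skipped") <- unlist(skipped)
  out
}

branch_gene_filter <- function(gene, cm) {
  tx <- rownames(gene)
  if (length(intersect(tx, clan_taxa(cm, "Protostomia"))) < 2L)
    return("fewer than 2 protostome taxa")
  if (length(intersect(tx, clan_taxa(cm, "Deuterostomia"))) < 2L)
    return("fewer than 2 deuterostome taxa")
  if (!length(intersect(tx, cm$Outgroup)))
    return("no outgroup taxon")
  NULL
}

#' Mean clade depths from the bilaterian ancestor
#'
#' Average root-to-tip distance from the Bilateria common ancestor to the
#' taxa of Protostomia, Chordata and Xenambulacraria, and from the same node
#' to each outgroup taxon. Groups with no taxa in the tree are omitted with
#' a warning.
#'
#' @inheritParams stem_branch_length
#' @return Data frame with columns `group`, `n_taxa`, `mean_depth`.
#' @export
clade_depth_summary <- function(tree, cm) {
  d <- root_to_tip_lengths(tree, cm, reference = "bilateria")
  groups <- c("Outgroup", "Protostomia", "Chordata", "Xenambulacraria")
  rows <- lapply(groups, function(g) {
    tx <- intersect(names(d), clan_taxa(cm, g))
    if (!length(tx)) {
      warning("no taxa for group ", g, call. = FALSE)
      return(NULL)
    }
    data.frame(group = g, n_taxa = length(tx), mean_depth = mean(d[tx]))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Dataset rate: tree length on a common taxon set
#'
#' Crops alignment and reference tree to the given taxa, optimizes branch
#' lengths on the induced topology, and returns the sum of branch lengths
#' (expected substitutions per site across the subtree).
#'
#' @inheritParams optimize_branch_lengths
#' @param reference_tree Reference topology containing the common taxa.
#' @param common_taxa Character vector (>= 4 taxa).
#' @export
dataset_rate <- function(aln, reference_tree, common_taxa, model,
                         tol = 1e-4, max_passes = 30L) {
  if (length(common_taxa) < 4L) stop_invalid("need at least 4 common taxa")
  miss <- setdiff(common_taxa, intersect(rownames(aln),
                                         reference_tree$tip.label))
  if (length(miss))
    stop_invalid("taxa missing from alignment or tree: ",
                 paste(miss, collapse = ", "))
  tr <- crop_tree(reference_tree, common_taxa)
  fit <- optimize_branch_lengths(crop_alignment(aln, common_taxa), tr,
                                 model, tol = tol, max_passes = max_passes)
  sum(fit$tree$edge.length)
}
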