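# Likelihood evaluation and fixed-topology branch-length optimization.

# Validate and assemble the argument bundle for the C++ engine.
engine_args <- function(aln, tree, model, what = "likelihood") {
  if (!inherits(aln, "aa_alignment")) stop_invalid("aln must be aa_alignment")
  if (!inherits(tree, "phylo")) stop_invalid("tree must be a phylo object")
  missing_taxa <- setdiff(tree$tip.label, rownames(aln))
  if (length(missing_taxa))
    stop_invalid("tree taxa absent from alignment: ",
                 paste(missing_taxa, collapse = ", "))
  if (is.null(tree$edge.length))
    stop_invalid("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop_invalid("negative branch length")
  attr(tree, "order") <- NULL   # never trust a precomputed edge order
  pt <- ape::reorder.phylo(tree, "postorder")
  codes <- aln_codes(aln)[pt$tip.label, , drop = FALSE]
  pat <- compress_patterns(codes)
  prep <- prepare_model(model)
  list(edge = pt$edge, elen = pt$edge.length, ntip = length(pt$tip.label),
       tipcodes = pat$codes, pw = pat$weights, map = pat$map, prep = prep,
       ptree = pt)
}

#' Log-likelihood of an alignment on a fixed tree
#'
#' Felsenstein pruning under a (possibly profile-mixture) LG-type model with
#' discrete-gamma rates. Per-site likelihoods average over mixture profiles
#' (by weight) and rate categories (equal weight); gaps and `X` contribute
#' all-ones partial vectors. The tree may be rooted or unrooted; by
#' reversibility the value does not depend on root placement.
#'
#' @param aln An [aa_alignment()]; must contain every tree tip (extra taxa
#'   are ignored).
#' @param tree A `phylo` tree with nonnegative branch lengths.
#' @param model A [subst_model()].
#' @param per_site Return the per-site log-likelihood vector?
#' @return A `lnl_result` list: `lnl`, `tree`, `model`, `per_site_lnl`.
#' @export
compute_lnL <- function(aln, tree, model, per_site = TRUE) {
  ea <- engine_args(aln, tree, model)
  res <- cpp_lnl(ea$edge, ea$elen, ea$ntip, ea$tipcodes, ea$prep$V,
                 ea$prep$Vi, ea$prep$lam, ea$prep$pimat, ea$prep$wk,
                 ea$prep$rates, ea$pw)
  structure(list(lnl = res$lnl, tree = tree, model = model,
                 per_site_lnl = if (per_site) res$site_lnl[ea$map] else NULL),
            class = "lnl_result")
}

#' @export
print.lnl_result <- function(x, ...) {
  cat(sprintf("lnL = %.4f (%d tips)\n", x$lnl, length(x$tree$tip.label)))
  invisible(x)
}

# Per-profile site log-likelihoods (K x n_patterns) plus pattern weights;
# used by the EM weight updates.
profile_site_lnl <- function(aln, tree, model) {
  ea <- engine_args(aln, tree, model)
  res <- cpp_lnl(ea$edge, ea$elen, ea$ntip, ea$tipcodes, ea$prep$V,
                 ea$prep$Vi, ea$prep$lam, ea$prep$pimat, ea$prep$wk,
                 ea$prep$rates, ea$pw, profile_loglik = TRUE)
  list(profile_lnl = res$profile_lnl, pw = ea$pw)
}

#' Find the edge subtending a given taxon set
#'
#' Returns the index (row of `tree$edge`) of the branch that separates
#' `taxa` from the rest of the tree, looking on both sides of each split, or
#' errors if no branch induces that bipartition.
#'
#' @param tree A `phylo` tree.
#' @param taxa Character vector of tip labels.
#' @export
edge_for_split <- function(tree, taxa) {
  tips <- tree$tip.label
  if (!all(taxa %in% tips))
    stop_invalid("taxa not in tree: ",
                 paste(setdiff(taxa, tips), collapse = ", "))
  target <- sort(match(taxa, tips))
  ntip <- length(tips)
  desc <- descendant_tips(tree)
  for (e in seq_len(nrow(tree$edge))) {
    v <- tree$edge[e, 2L]
    d <- sort(desc[[v]])
    if (identical(d, target) ||
        identical(sort(setdiff(seq_len(ntip), d)), target))
      return(e)
  }
  stop_invalid("no branch induces the split defined by the given taxa")
}

# Canonical split key per edge: the tip-index set on the side of the edge
# not containing tip 1, as a string.  Comparable across rootings of the
# same topology (tip numbering preserved).
edge_split_keys <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- descendant_tips(tree)
  vapply(seq_len(nrow(tree$edge)), function(e) {
    d <- sort(desc[[tree$edge[e, 2L]]])
    if (1L %in% d) d <- sort(setdiff(seq_len(ntip), d))
    paste(d, collapse = ",")
  }, character(1L))
}

# Tip indices below each node (tips map to themselves).
descendant_tips <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  attr(tree, "order") <- NULL
  pt <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (e in seq_len(nrow(pt$edge))) {
    u <- pt$edge[e, 1L]; v <- pt$edge[e, 2L]
    desc[[u]] <- c(desc[[u]], desc[[v]])
  }
  desc
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate ascent: each free branch is optimized in turn by bounded Brent
#' search (bounds `[min_edge, max_edge]`, flat regions resolving toward the
#' lower bound), iterating passes over all branches until the log-likelihood
#' improves by less than `tol` nats or `max_passes` is reached. The returned
#' log-likelihood is never below the starting one. Branches listed in
#' `fixed_edges` are pinned at their input lengths (used, e.g., to hold a
#' collapsed stem at zero).
#'
#' @inheritParams compute_lnL
#' @param topology A `phylo` tree whose branch lengths serve as the starting
#'   point (missing lengths start at 0.05).
#' @param fixed_edges Integer indices of rows of `topology$edge` to pin.
#' @param tol Convergence tolerance in nats (default 1e-4).
#' @param max_passes Maximum optimization sweeps.
#' @param min_edge,max_edge Branch-length bounds for free edges.
#' @return A `lnl_result` with the optimized tree, plus `converged`,
#'   `passes`, and the starting `lnl0`. Non-convergence sets
#'   `converged = FALSE` (with a warning) rather than failing.
#' @export
optimize_branch_lengths <- function(aln, topology, model, fixed_edges = NULL,
                                    tol = 1e-4, max_passes = 30L,
                                    min_edge = 1e-8, max_edge = 20,
                                    per_site = FALSE) {
  if (is.null(topology$edge.length))
    topology$edge.length <- rep(0.05, nrow(topology$edge))
  # A rooted binary tree's two root branches are confounded (only their sum
  # is identifiable for a reversible model): optimize the unrooted tree and
  # share the merged length back proportionally.
  root_edges <- which(topology$edge[, 1L] ==
                        length(topology$tip.label) + 1L)
  if (ape::is.rooted(topology) && length(topology$tip.label) >= 3L &&
      length(root_edges) == 2L && !any(fixed_edges %in% root_edges)) {
    ur <- ape::unroot(topology)
    key_in <- edge_split_keys(topology)
    key_ur <- edge_split_keys(ur)
    map <- match(key_in, key_ur)      # root edges map to the merged edge
    fit <- optimize_branch_lengths(aln, ur, model,
                                   fixed_edges = map[fixed_edges],
                                   tol = tol, max_passes = max_passes,
                                   min_edge = min_edge,
                                   max_edge = max_edge,
                                   per_site = per_site)
    out_tree <- topology
    out_tree$edge.length <- fit$tree$edge.length[map]
    w0 <- topology$edge.length[root_edges]
    share <- if (sum(w0) > 0) w0 / sum(w0) else c(0.5, 0.5)
    out_tree$edge.length[root_edges] <-
      fit$tree$edge.length[map[root_edges[1L]]] * share
    fit$tree <- out_tree
    return(fit)
  }
  ea <- engine_args(aln, topology, model)
  # Map fixed edge indices through the postorder row permutation.
  key <- function(e) paste(e[, 1L], e[, 2L])
  perm <- match(key(ea$edge), key(topology$edge))
  fixed <- rep(FALSE, nrow(ea$edge))
  if (length(fixed_edges)) fixed[match(fixed_edges, perm)] <- TRUE
  elen0 <- ea$elen
  elen0[!fixed] <- pmin(pmax(elen0[!fixed], min_edge), max_edge)
  res <- cpp_optimize_edges(ea$edge, elen0, ea$ntip, ea$tipcodes, ea$prep$V,
                            ea$prep$Vi, ea$prep$lam, ea$prep$pimat,
                            ea$prep$wk, ea$prep$rates, ea$pw, fixed,
                            min_edge, max_edge, tol, as.integer(max_passes))
  if (!res$converged)
    warning("branch-length optimization did not converge in ", max_passes,
            " passes", call. = FALSE)
  out_tree <- topology
  out_tree$edge.length[perm] <- res$elen
  psl <- NULL
  if (per_site) {
    r2 <- cpp_lnl(ea$edge, res$elen, ea$ntip, ea$tipcodes, ea$prep$V,
                  ea$prep$Vi, ea$prep$lam, ea$prep$pimat, ea$prep$wk,
                  ea$prep$rates, ea$pw)
    psl <- r2$site_lnl[ea$map]
  }
  structure(list(lnl = res$lnl, tree = out_tree, model = model,
                 per_site_lnl = psl, lnl0 = res$lnl0,
                 converged = res$converged, passes = res$passes),
            class = "lnl_result")
}
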