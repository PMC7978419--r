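# Simulation-based diagnosis of long-branch attraction: fit/simulate under
# the three candidate arrangements, reinfer under matched and violated
# models with and without long/short-branch taxa, and tally recoveries.
# Also the ML cross-validation model-fit ladder.

#' Select the best-supported of three hypothesis topologies
#'
#' Optimizes branch lengths on each hypothesis tree (cropped to the
#' alignment's taxa) under the given model and returns the label of the
#' maximum-likelihood topology. Ties closer than `tie_tol` nats resolve in
#' label order and are flagged.
#'
#' @param aln An [aa_alignment()].
#' @param hypotheses A [hypothesis_trees()] result.
#' @param model A [subst_model()].
#' @param refit_weights For mixture models, refit the mixture weights by EM
#'   (between two branch-optimization rounds) on each hypothesis.
#' @param tol,max_passes Optimizer settings.
#' @param tie_tol Log-likelihood tie tolerance in nats.
#' @return The selected label, with attributes `lnls` and `tie`.
#' @export
select_topology <- function(aln, hypotheses, model, refit_weights = FALSE,
                            tol = 1e-3, max_passes = 15L, tie_tol = 1e-6) {
  first_fit <- NULL
  lnls <- vapply(hypotheses$labels, function(lb) {
    tr <- crop_tree(hypotheses$trees[[lb]], rownames(aln))
    # Warm-start later hypotheses from the first fit's shared splits.
    if (!is.null(first_fit)) tr <- borrow_split_lengths(tr, first_fit)
    fit <- suppressWarnings(
      optimize_branch_lengths(aln, tr, model, tol = tol,
                              max_passes = max_passes))
    if (is.null(first_fit)) first_fit <<- fit$tree
    if (!refit_weights || nrow(model$profiles) == 1L) return(fit$lnl)
    # Coordinate ascent over mixture weights and branch lengths until the
    # joint fit stops improving.
    cur <- fit$lnl
    tree <- fit$tree
    m2 <- model
    for (round in 1:6) {
      em <- em_weights(aln, tree, m2)
      if (em$lnl > cur) {
        m2$weights <- em$weights
        cur <- em$lnl
      }
      fit <- suppressWarnings(
        optimize_branch_lengths(aln, tree, m2, tol = tol,
                                max_passes = max_passes))
      gain <- fit$lnl - cur
      if (fit$lnl > cur) {
        cur <- fit$lnl
        tree <- fit$tree
      }
      if (gain < 10 * tol) break
    }
    cur
  }, numeric(1L))
  best <- max(lnls)
  tie <- sum(lnls > best - tie_tol) > 1L
  sel <- hypotheses$labels[which(lnls > best - tie_tol)[1L]]
  structure(sel, lnls = lnls, tie = tie)
}

# Copy branch lengths from `source` onto every edge of `target` that
# induces the same (label-based) bipartition; other edges keep their
# current lengths.
borrow_split_lengths <- function(target, source) {
  kt <- split_label_keys(target)
  ks <- split_label_keys(source)
  hit <- match(kt, ks)
  ok <- !is.na(hit)
  target$edge.length[ok] <- source$edge.length[hit[ok]]
  target
}

# Canonical per-edge split keys by tip label, comparable across trees on
# the same taxon set.
split_label_keys <- function(tree) {
  labs <- sort(tree$tip.label)
  desc <- descendant_tips(tree)
  vapply(seq_len(nrow(tree$edge)), function(e) {
    s <- sort(tree$tip.label[desc[[tree$edge[e, 2L]]]])
    if (labs[1L] %in% s) s <- setdiff(labs, s)
    paste(s, collapse = "|")
  }, character(1L))
}

#' Rank-based taxon removal sets
#'
#' Ranks the protostome and outgroup taxa by their distance from the
#' bilaterian common ancestor and returns the `k` longest- or
#' shortest-branched, never removing the last present member of a clan.
#' Ties break by taxon name.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param cm A [clade_map()].
#' @param k Number of taxa to remove (`0` gives an empty set).
#' @param mode `"longest"` or `"shortest"`.
#' @return Character vector of `k` taxon names.
#' @export
taxon_removal_sets <- function(tree, cm, k, mode = c("longest",
                                                     "shortest")) {
  mode <- match.arg(mode)
  if (k == 0L) return(character())
  cand <- c(clan_taxa(cm, "Protostomia", tree),
            clan_taxa(cm, "Outgroup", tree))
  if (k > length(cand) - 2L)
    stop_invalid("k = ", k, " exceeds removable protostome+outgroup taxa")
  d <- root_to_tip_lengths(tree, cm)[cand]
  ord <- if (mode == "longest") order(-d, names(d)) else order(d, names(d))
  ranked <- names(d)[ord]
  clan_of <- function(tx) names(cm)[vapply(cm, function(s) tx %in% s,
                                           logical(1L))][1L]
  left <- table(vapply(cand, clan_of, character(1L)))
  out <- character()
  for (tx in ranked) {
    if (length(out) == k) break
    cl <- clan_of(tx)
    if (left[[cl]] <= 1L) next
    out <- c(out, tx)
    left[[cl]] <- left[[cl]] - 1L
  }
  if (length(out) < k)
    stop_invalid("cannot remove ", k, " taxa while keeping every clan")
  out
}

#' Configuration for a topology-recovery simulation experiment
#'
#' Defaults describe the desk-scale study: 20 replicates of 2,000 sites per
#' generating topology, a 10-profile Dirichlet(0.2) mixture with gamma
#' shape 0.7 over the default clade-structured tree, and all four
#' reinference conditions.
#'
#' @param topologies Generating topologies, subset of `DM`, `D1`, `D2`.
#' @param n_replicates Replicates per topology.
#' @param n_sites Sites per replicate.
#' @param tree_config A [clade_tree_config()] (its `topology` field is
#'   overridden per generating topology).
#' @param profiles Generating profile library (default: 10 profiles from
#'   [make_profile_library()] with `profile_seed`).
#' @param profile_seed Seed for the default profile library.
#' @param alpha,ncat Generating gamma shape and category count.
#' @param conditions Reinference conditions, subset of `Het` (matched
#'   mixture, weights refit), `Hom` (single-profile LG+F+G), `HomNL` (Hom
#'   after removing the `removal_k` longest protostome+outgroup taxa),
#'   `HomNS` (Hom after removing the `removal_k` shortest).
#' @param removal_k Taxa removed in `HomNL`/`HomNS` (default: half the
#'   protostome+outgroup taxa).
#' @param seed_offsets Named per-topology seed offsets; replicate `r` of
#'   topology `T` is simulated with seed `base_seed + seed_offsets[T] + r`.
#' @param base_seed Base seed added to every replicate seed.
#' @param het_refit_weights Refit the mixture weights by EM in the `Het`
#'   condition (default `FALSE`: the matched generating model scores the
#'   hypotheses directly).
#' @param tol,max_passes Optimizer settings for the reinference fits.
#' @return An `lba_config` list.
#' @export
lba_config <- function(topologies = c("DM", "D1", "D2"), n_replicates = 20L,
                       n_sites = 2000L, tree_config = clade_tree_config(),
                       profiles = NULL, profile_seed = 42L, alpha = 0.7,
                       ncat = 4L,
                       conditions = c("Het", "Hom", "HomNL", "HomNS"),
                       removal_k = NULL,
                       seed_offsets = c(DM = 100L, D1 = 200L, D2 = 300L),
                       base_seed = 0L, het_refit_weights = FALSE,
                       tol = 1e-3, max_passes = 30L) {
  stopifnot(n_replicates >= 1L, length(conditions) >= 1L)
  topologies <- match.arg(topologies, several.ok = TRUE)
  conditions <- match.arg(conditions, several.ok = TRUE)
  if (is.null(profiles))
    profiles <- make_profile_library(10L, 0.2, seed = profile_seed)
  structure(list(topologies = topologies,
                 n_replicates = as.integer(n_replicates),
                 n_sites = as.integer(n_sites), tree_config = tree_config,
                 profiles = profiles, alpha = alpha,
                 ncat = as.integer(ncat), conditions = conditions,
                 removal_k = removal_k, seed_offsets = seed_offsets,
                 base_seed = as.integer(base_seed),
                 het_refit_weights = het_refit_weights, tol = tol,
                 max_passes = as.integer(max_passes)),
            class = "lba_config")
}

#' Run the topology-recovery simulation experiment
#'
#' For each generating topology: simulate replicate alignments under the
#' site-heterogeneous generating model, then reinfer the topology under
#' each requested condition by constrained choice among the three
#' clan-level resolutions ([select_topology()]), and tally the selections.
#' The site-homogeneous conditions estimate their gamma shape once per
#' replicate (LG+G fit on the first hypothesis) and their "+F" frequencies
#' from the (cropped) replicate alignment.
#'
#' @param config An [lba_config()].
#' @param verbose Print per-replicate progress lines?
#' @return A `recovery_tally`: list with `counts` (generating x condition x
#'   selected array), `n_replicates`, and `log` (per-replicate data frame).
#' @export
run_lba_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "lba_config"))
  labels <- c("DM", "D1", "D2")
  counts <- array(0L, dim = c(length(config$topologies),
                              length(config$conditions), 3L),
                  dimnames = list(generating = config$topologies,
                                  condition = config$conditions,
                                  selected = labels))
  logs <- list()
  gen_model <- subst_model(config$profiles, alpha = config$alpha,
                           ncat = config$ncat)
  cfg_dm <- config$tree_config
  cfg_dm$topology <- "DM"
  ref <- make_clade_tree(cfg_dm)
  cm <- ref$clade_map
  hyp <- hypothesis_trees(ref$tree, cm, focus = "deuterostome")
  n_po <- length(clan_taxa(cm, "Protostomia")) + length(cm$Outgroup)
  k <- config$removal_k %||% (n_po %/% 2L)
  for (gt in config$topologies) {
    cfg <- config$tree_config
    cfg$topology <- gt
    gen <- make_clade_tree(cfg)
    removals <- list(
      HomNL = if ("HomNL" %in% config$conditions)
        taxon_removal_sets(gen$tree, cm, k, "longest") else NULL,
      HomNS = if ("HomNS" %in% config$conditions)
        taxon_removal_sets(gen$tree, cm, k, "shortest") else NULL)
    for (r in seq_len(config$n_replicates)) {
      seed_r <- config$base_seed + config$seed_offsets[[gt]] + r
      aln <- simulate_alignment(gen$tree, gen_model, config$n_sites,
                                seed = seed_r,
                                name = sprintf("%s_rep%03d", gt, r))
      for (cond in config$conditions) {
        a <- aln
        if (cond %in% c("HomNL", "HomNS"))
          a <- crop_alignment(aln, setdiff(rownames(aln),
                                           removals[[cond]]))
        if (cond == "Het") {
          # Matched site-heterogeneous reinference: the generating profile
          # library, weights and shape.
          model <- gen_model
          sel <- select_topology(a, hyp, model,
                                 refit_weights = config$het_refit_weights,
                                 tol = config$tol,
                                 max_passes = config$max_passes)
        } else {
          # Site-homogeneous LG+F+G: frequencies and gamma shape estimated
          # from the (cropped) replicate data.
          tr0 <- crop_tree(hyp$trees[[1L]], rownames(a))
          alpha_hom <- suppressWarnings(
            fit_model(a, tr0, "LG+G", ncat = config$ncat,
                      max_outer = 1L, tol = config$tol,
                      max_passes = min(8L, config$max_passes)
                      )$model$alpha)
          model <- lg_model(empirical_frequencies(a), alpha = alpha_hom,
                            ncat = config$ncat)
          sel <- select_topology(a, hyp, model, tol = config$tol,
                                 max_passes = config$max_passes)
        }
        counts[gt, cond, as.character(sel)] <-
          counts[gt, cond, as.character(sel)] + 1L
        lnls <- attr(sel, "lnls")
        logs[[length(logs) + 1L]] <- data.frame(
          generating = gt, condition = cond, replicate = r, seed = seed_r,
          lnl_DM = lnls[["DM"]], lnl_D1 = lnls[["D1"]],
          lnl_D2 = lnls[["D2"]], selected = as.character(sel),
          tie = attr(sel, "tie"))
        if (verbose)
          message(sprintf("%s rep %d %s -> %s", gt, r, cond,
                          as.character(sel)))
      }
    }
  }
  structure(list(counts = counts, n_replicates = config$n_replicates,
                 log = do.call(rbind, logs)),
            class = "recovery_tally")
}

#' @export
print.recovery_tally <- function(x, ...) {
  cat("Topology recovery tally (rows: generating; slices: condition)\n")
  print(x$counts)
  invisible(x)
}

#' Percentage of replicates selecting a given topology
#'
#' @param tally A `recovery_tally`.
#' @param generating Generating topology label.
#' @param condition Reinference condition.
#' @param selected Selected topology label.
#' @export
recovery_percent <- function(tally, generating, condition, selected) {
  100 * tally$counts[generating, condition, selected] /
    sum(tally$counts[generating, condition, ])
}

#' Site-subsampling cross-validation of the model ladder
#'
#' For each fold, disjoint training and test site sets are sampled; each
#' model of the ladder is fitted on the training sites (topology fixed,
#' branch lengths and parameters estimated) and the held-out sites are
#' scored at the fitted parameters.
#'
#' @inheritParams fit_model
#' @param models Character vector of ladder rungs (see [fit_model()]).
#' @param n_folds Number of folds.
#' @param train_sites,test_sites Sites per training and test set.
#' @param seed Integer seed (fold `f` uses `seed + f`).
#' @return Data frame `(model, fold, test_lnl)` with a `summary` attribute
#'   of per-model means and SDs.
#' @export
cross_validation <- function(aln, topology,
                             models = c("LG", "LG+G", "MIX+LG+G"),
                             profiles = NULL, n_folds = 10L,
                             train_sites = 10000L, test_sites = 2000L,
                             seed = 1L, ncat = 4L, tol = 1e-3,
                             max_passes = 10L, max_outer = 3L) {
  if (train_sites + test_sites > n_sites(aln))
    stop_invalid("train + test sites exceed the alignment length")
  rows <- list()
  for (f in seq_len(n_folds)) {
    idx <- with_seed(seed + f,
                     sample.int(n_sites(aln), train_sites + test_sites))
    train <- aa_alignment(unclass(aln)[, idx[seq_len(train_sites)],
                                       drop = FALSE], name = "train")
    test <- aa_alignment(unclass(aln)[, idx[train_sites + seq_len(
      test_sites)], drop = FALSE], name = "test")
    for (m in models) {
      fit <- fit_model(train, topology, m, profiles = profiles,
                       ncat = ncat, tol = tol, max_passes = max_passes,
                       max_outer = max_outer)
      score <- compute_lnL(test, fit$tree, fit$model,
                           per_site = FALSE)$lnl
      rows[[length(rows) + 1L]] <- data.frame(model = m, fold = f,
                                              test_lnl = score)
    }
  }
  out <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(out$test_lnl, out$model), function(x)
    data.frame(mean = mean(x), sd = stats::sd(x))))
  agg <- data.frame(model = rownames(agg), agg, row.names = NULL)
  attr(out, "summary") <- agg[match(models, agg$model), ]
  out
}
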