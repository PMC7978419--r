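# Forward sequence simulation along a tree under a profile-mixture model.

#' Simulate an amino-acid alignment on a tree
#'
#' Per site: a profile is drawn by mixture weight and a gamma-rate category
#' uniformly; the root state is drawn from the profile; states then evolve
#' along each branch with transition matrices `exp(Q t r)`. The process is
#' reversible, so the (arbitrary) root placement does not affect the
#' distribution. Output is deterministic given `seed`, and the caller's RNG
#' state is left untouched.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param model A [subst_model()].
#' @param n_sites Number of sites to simulate (>= 1).
#' @param seed Integer seed.
#' @param rate_multiplier Scales every branch length (per-gene rate).
#' @param name Name for the resulting alignment.
#' @return An [aa_alignment()].
#' @export
simulate_alignment <- function(tree, model, n_sites, seed,
                               rate_multiplier = 1, name = "sim") {
  if (!is.numeric(n_sites) || n_sites < 1)
    stop_invalid("n_sites must be >= 1")
  n_sites <- as.integer(n_sites)
  if (is.null(tree$edge.length)) stop_invalid("tree has no branch lengths")
  prep <- prepare_model(model)
  K <- length(prep$V)
  C <- length(prep$rates)
  attr(tree, "order") <- NULL
  pt <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(pt$tip.label)
  nnode <- max(pt$edge)
  root <- setdiff(pt$edge[, 1L], pt$edge[, 2L])[1L]
  with_seed(seed, {
    prof <- sample.int(K, n_sites, replace = TRUE, prob = prep$wk)
    cat_ <- sample.int(C, n_sites, replace = TRUE)
    combo <- (prof - 1L) * C + cat_
    states <- matrix(0L, nnode, n_sites)
    for (k in seq_len(K)) {
      idx <- which(prof == k)
      if (length(idx))
        states[root, idx] <- sample.int(20L, length(idx), replace = TRUE,
                                        prob = prep$pimat[, k])
    }
    for (e in rev(seq_len(nrow(pt$edge)))) {
      u <- pt$edge[e, 1L]; v <- pt$edge[e, 2L]
      for (m in unique(combo)) {
        idx <- which(combo == m)
        k <- (m - 1L) %/% C + 1L
        r <- prep$rates[(m - 1L) %% C + 1L]
        t <- pt$edge.length[e] * r * rate_multiplier
        P <- prep$V[[k]] %*% (exp(prep$lam[[k]] * t) * prep$Vi[[k]])
        P[P < 0] <- 0
        P <- P / rowSums(P)
        ps <- states[u, idx]
        for (i in unique(ps)) {
          ii <- idx[ps == i]
          states[v, ii] <- sample.int(20L, length(ii), replace = TRUE,
                                      prob = P[i, ])
        }
      }
    }
    res <- matrix(AA_ALPHABET[states[seq_len(ntip), , drop = FALSE]],
                  ntip, n_sites, dimnames = list(pt$tip.label, NULL))
    aa_alignment(res, name = name)
  })
}
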