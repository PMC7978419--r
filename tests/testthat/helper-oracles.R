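# Independent oracles and small fixtures used across the test files.

# Likelihood oracle: exhaustive ancestral-state enumeration with
# matrix-exponential transition probabilities (Matrix::expm), fully
# independent of the package's eigendecomposition pruning path.
brute_force_lnl <- function(aln, tree, model) {
  prep <- lbadiag:::prepare_model(model)
  codes <- lbadiag:::aln_codes(aln)
  pt <- ape::reorder.phylo(tree, "postorder")
  codes <- codes[pt$tip.label, , drop = FALSE]
  K <- length(prep$V)
  C <- length(prep$rates)
  ntip <- nrow(codes)
  root <- setdiff(pt$edge[, 1], pt$edge[, 2])[1]
  Qs <- lapply(seq_len(K), function(k)
    lbadiag:::profile_rate_matrix(model$exch, prep$pimat[, k]))
  total <- 0
  for (s in seq_len(ncol(codes))) {
    Lsite <- 0
    for (k in seq_len(K)) for (cc in seq_len(C)) {
      cond <- function(node) {
        if (node <= ntip) {
          v <- rep(1, 20)
          if (codes[node, s] > 0) {
            v <- rep(0, 20)
            v[codes[node, s]] <- 1
          }
          return(v)
        }
        out <- rep(1, 20)
        for (e in which(pt$edge[, 1] == node)) {
          P <- as.matrix(Matrix::expm(Qs[[k]] * pt$edge.length[e] *
                                        prep$rates[cc]))
          out <- out * as.vector(P %*% cond(pt$edge[e, 2]))
        }
        out
      }
      Lsite <- Lsite + prep$wk[k] / C * sum(prep$pimat[, k] * cond(root))
    }
    total <- total + log(Lsite)
  }
  total
}

# Graph-based path-length oracle via the full node distance matrix.
dist_oracle <- function(tree, a, b) ape::dist.nodes(tree)[a, b]

# A small random alignment over a given tree/model, fixed seed.
toy_alignment <- function(tree, model, n = 30, seed = 1) {
  simulate_alignment(tree, model, n, seed = seed)
}

# The worked seven-taxon tree used in several examples: protostome stem
# 0.4, deuterostome stem 0.2, chordate/xenambulacrarian stems 0.1.
worked_tree <- function() {
  parse_newick(paste0("(((P1:1,P2:1):0.4,((C1:1,C2:1):0.1,",
                      "(X1:1,X2:1):0.1):0.2):0.3,O1:2);"))
}

worked_map <- function() {
  clade_map(outgroup = "O1", lophotrochozoa = "P1", ecdysozoa = "P2",
            chordata = c("C1", "C2"), xenambulacraria = c("X1", "X2"))
}

# Default 20-taxon clan map matching make_clade_tree labels.
default_map <- function(n = 4) {
  clade_map(paste0("O", 1:n), paste0("L", 1:n), paste0("E", 1:n),
            paste0("C", 1:n), paste0("X", 1:n))
}

# Stem length of the branch whose split isolates exactly `taxa`.
stem_of <- function(tree, taxa) {
  tree$edge.length[edge_for_split(tree, taxa)]
}

random_model <- function(K = 2, alpha = NULL, ncat = 1, seed = 1) {
  prof <- make_profile_library(K, 0.5, seed = seed)
  subst_model(prof, alpha = alpha, ncat = ncat)
}
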