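# Substitution models: LG exchangeabilities with one stationary frequency
# vector (site-homogeneous, "+F") or a K-profile mixture of frequency vectors
# (site-heterogeneous), crossed with equal-weight discrete-gamma rates.

#' Discrete-gamma rate categories
#'
#' Splits a mean-1 gamma distribution with shape `alpha` into `K` categories
#' of equal probability and returns the mean rate of each (Yang's
#' discretization), renormalized so the category mean is exactly 1.
#'
#' @param alpha Positive gamma shape (smaller = more rate variation).
#' @param K Number of categories (>= 1).
#' @return Nondecreasing numeric vector of `K` rates with mean 1.
#' @export
discretize_gamma <- function(alpha, K) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0)
    stop_invalid("alpha must be a positive number")
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K))
    stop_invalid("K must be a positive integer")
  K <- as.integer(K)
  if (K == 1L) return(1)
  # Mean of each equal-probability slice of Gamma(alpha, rate = alpha):
  # using the identity E[X; X in (a,b)] = I(b; alpha+1) - I(a; alpha+1).
  b <- qgamma(seq(0, 1, length.out = K + 1L), shape = alpha, rate = alpha)
  r <- K * diff(pgamma(b, shape = alpha + 1, rate = alpha))
  r / mean(r)
}

#' Construct a substitution model
#'
#' @param profiles Numeric K x 20 matrix of amino-acid frequency profiles
#'   (rows sum to 1; column order `ARNDCQEGHILKMFPSTWYV`), or a single
#'   frequency vector of length 20.
#' @param weights Profile mixture weights (default uniform); must sum to 1.
#' @param alpha Discrete-gamma shape, or `NULL` for rate homogeneity.
#' @param ncat Number of gamma categories (ignored when `alpha` is `NULL`).
#' @param exch Symmetric 20 x 20 exchangeability matrix (default LG).
#' @return An object of class `subst_model`.
#' @details Each profile's rate matrix is calibrated to an expected rate of 1
#'   at stationarity, so branch lengths are in expected substitutions per
#'   site under every mixture component. Profile entries are floored at 1e-6
#'   (and rows renormalized) for numerical conditioning of the
#'   eigendecomposition.
#' @export
subst_model <- function(profiles, weights = NULL, alpha = NULL, ncat = 4L,
                        exch = lg_exchangeabilities()) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1L)
  profiles <- as.matrix(profiles)
  if (ncol(profiles) != 20L) stop_invalid("profiles must have 20 columns")
  if (any(profiles < 0)) stop_invalid("profile frequencies must be >= 0")
  if (any(abs(rowSums(profiles) - 1) > 1e-8))
    stop_invalid("profile rows must sum to 1")
  profiles <- pmax(profiles, 1e-6)
  profiles <- profiles / rowSums(profiles)
  K <- nrow(profiles)
  weights <- weights %||% rep(1 / K, K)
  if (length(weights) != K || any(weights < 0) ||
      abs(sum(weights) - 1) > 1e-8)
    stop_invalid("weights must be a length-K simplex vector")
  weights <- weights / sum(weights)
  if (!is.null(alpha)) {
    if (alpha <= 0) stop_invalid("alpha must be positive")
  } else ncat <- 1L
  if (!isTRUE(all.equal(dim(exch), c(20L, 20L))) ||
      max(abs(exch - t(exch))) > 1e-10 || any(exch < 0))
    stop_invalid("exch must be a symmetric nonnegative 20 x 20 matrix")
  colnames(profiles) <- AA_ALPHABET
  structure(list(exch = exch, profiles = profiles, weights = weights,
                 alpha = alpha, ncat = as.integer(ncat)),
            class = "subst_model")
}

#' @export
print.subst_model <- function(x, ...) {
  cat(sprintf("subst_model: %d profile(s)%s\n", nrow(x$profiles),
              if (is.null(x$alpha)) ", rate-homogeneous"
              else sprintf(", gamma(alpha=%.4g) x %d categories", x$alpha,
                           x$ncat)))
  invisible(x)
}

#' Site-homogeneous LG model
#'
#' Convenience constructor for LG with a single frequency vector, optionally
#' with discrete-gamma rates.
#'
#' @param freqs Frequency vector (default: the LG stationary frequencies).
#' @param alpha,ncat Gamma shape and category count (see [subst_model()]).
#' @export
lg_model <- function(freqs = LG_FREQS, alpha = NULL, ncat = 4L) {
  subst_model(matrix(freqs / sum(freqs), 1L), alpha = alpha, ncat = ncat)
}

#' Observed amino-acid frequencies of an alignment
#'
#' Global "+F" frequencies: residue counts (gaps and `X` excluded) with a
#' pseudocount added to every residue.
#'
#' @param aln An `aa_alignment`.
#' @param pseudocount Added to each of the 20 counts (default 1).
#' @return Named frequency vector of length 20.
#' @export
empirical_frequencies <- function(aln, pseudocount = 1) {
  cnt <- table(factor(unclass(aln), levels = AA_ALPHABET))
  f <- as.numeric(cnt) + pseudocount
  setNames(f / sum(f), AA_ALPHABET)
}

#' Read / write a profile library as TSV
#'
#' K rows x 20 columns, header row of one-letter residue codes in the fixed
#' order `ARNDCQEGHILKMFPSTWYV`.
#'
#' @param path File path.
#' @export
read_profile_library <- function(path) {
  d <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  if (!identical(colnames(d), AA_ALPHABET))
    stop_invalid("profile library header must be ",
                 paste(AA_ALPHABET, collapse = ""))
  as.matrix(d)
}

#' @rdname read_profile_library
#' @param profiles K x 20 matrix of profiles.
#' @export
write_profile_library <- function(profiles, path) {
  colnames(profiles) <- AA_ALPHABET
  write.table(format(profiles, digits = 10), path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Calibrated rate matrix for one profile: Q_ij = s_ij pi_j, diagonal set so
# rows sum to 0, scaled to unit expected rate at stationarity.
profile_rate_matrix <- function(exch, pi) {
  Q <- exch * rep(pi, each = 20L)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  rate <- -sum(pi * diag(Q))
  Q / rate
}

# Eigendecomposition bundle consumed by the C++ engine: for each profile,
# P(t) = V diag(exp(lam t)) Vi via the symmetrized reversible form.
prepare_model <- function(model) {
  K <- nrow(model$profiles)
  V <- Vi <- lam <- vector("list", K)
  for (k in seq_len(K)) {
    pi <- model$profiles[k, ]
    Q <- profile_rate_matrix(model$exch, pi)
    sq <- sqrt(pi)
    B <- Q * (sq %o% (1 / sq))
    B <- (B + t(B)) / 2
    eg <- eigen(B, symmetric = TRUE)
    V[[k]] <- eg$vectors / sq
    Vi[[k]] <- t(eg$vectors) * rep(sq, each = 20L)
    lam[[k]] <- eg$values
  }
  rates <- if (is.null(model$alpha)) 1 else
    discretize_gamma(model$alpha, model$ncat)
  list(V = V, Vi = Vi, lam = lam, pimat = t(model$profiles),
       wk = model$weights, rates = rates)
}

#' Transition probability matrix under one mixture component
#'
#' Mostly useful for checking and simulation: `P(t)` for profile `k` of the
#' model, with rows renormalized after clamping roundoff negatives at zero.
#'
#' @param model A `subst_model`.
#' @param t Branch length (expected substitutions per site at rate 1).
#' @param k Profile index.
#' @export
transition_matrix <- function(model, t, k = 1L) {
  if (t < 0) stop_invalid("branch length must be >= 0")
  prep <- prepare_model(model)
  P <- prep$V[[k]] %*% (exp(prep$lam[[k]] * t) * prep$Vi[[k]])
  P[P < 0] <- 0
  P / rowSums(P)
  }
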