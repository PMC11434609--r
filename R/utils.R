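# Internal helpers shared across modules.

# Run code under a local, restored RNG state. All user-facing randomness in
# the package flows through this so a master seed gives bit-identical output.
.withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

.logdet <- function(x) {
  as.numeric(determinant(x, logarithm = TRUE)$modulus)
}

# log multivariate gamma function, log Gamma_D(a)
.lmvgamma <- function(a, D) {
  (D * (D - 1) / 4) * log(pi) + sum(lgamma(a + (1 - seq_len(D)) / 2))
}

# Cholesky with a trace-scaled ridge fallback; used wherever a posterior
# scatter can go numerically non-PD.
.safeChol <- function(S, context = "covariance") {
  ch <- try(chol(S), silent = TRUE)
  if (inherits(ch, "try-error")) {
    ridge <- 1e-8 * sum(diag(S)) / nrow(S)
    warning(sprintf("%s regularized with ridge %.3g", context, ridge),
            call. = FALSE)
    ch <- chol(S + diag(ridge, nrow(S)))
  }
  ch
}

.symmetrize <- function(S) (S + t(S)) / 2

# Draw n rows from N(mean, cov) given an upper-triangular Cholesky factor.
.rmvnormChol <- function(n, mean, cholU) {
  D <- length(mean)
  z <- matrix(stats::rnorm(n * D), n, D)
  sweep(z %*% cholU, 2L, mean, "+")
}

# Multivariate normal log-density for a matrix of rows.
.logDmvnorm <- function(X, mean, cov) {
  D <- ncol(X)
  ch <- .safeChol(cov)
  xc <- sweep(X, 2L, mean)
  y <- backsolve(ch, t(xc), transpose = TRUE)
  -0.5 * (D * log(2 * pi) + 2 * sum(log(diag(ch))) + colSums(y^2))
}

# All permutations of 1..n (n <= 9), in lexicographic order.
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  r <- 0L
  for (first in seq_len(n)) {
    rest <- seq_len(n)[-first]
    for (i in seq_len(nrow(sub))) {
      r <- r + 1L
      out[r, ] <- c(first, rest[sub[i, ]])
    }
  }
  out
}

#' Align estimated states to reference states
#'
#' Finds the state relabeling that best matches a set of estimated state
#' means to reference means, by exhaustive search over all permutations
#' (exact optimal assignment; practical for K <= 9). The cost of pairing an
#' estimated state with a reference state is `1 - cor(est_mean, ref_mean)`,
#' so the optimum maximizes the summed Pearson correlation.
#'
#' @param estMeans K x D matrix of estimated state means.
#' @param refMeans K x D matrix of reference state means.
#' @return Integer permutation `p` such that estimated state `p[k]` matches
#'   reference state `k`; attribute `"correlations"` holds the matched
#'   per-state correlations.
#' @export
matchStates <- function(estMeans, refMeans) {
  K <- nrow(refMeans)
  stopifnot(nrow(estMeans) == K, K <= 9L)
  cmat <- suppressWarnings(stats::cor(t(refMeans), t(estMeans))) # [ref, est]
  sim <- cmat
  if (any(!is.finite(sim))) {
    # profile correlation is undefined for (near-)constant mean vectors
    # (possible at very low D); fall back to negative Euclidean distance
    sim <- -as.matrix(stats::dist(rbind(refMeans, estMeans)))[
      seq_len(K), K + seq_len(K), drop = FALSE]
  }
  perms <- .permutations(K)
  scores <- numeric(nrow(perms))
  for (i in seq_len(nrow(perms))) {
    scores[i] <- sum(sim[cbind(seq_len(K), perms[i, ])])
  }
  best <- perms[which.max(scores), ]
  structure(best, correlations = cmat[cbind(seq_len(K), best)])
}

#' Permute the state indices of a fitted model
#'
#' Relabels states so that new state `k` is old state `perm[k]`. Free energy
#' and all inferences are invariant under this relabeling.
#'
#' @param model an [HmmModel-class].
#' @param perm integer permutation of `1:K`.
#' @return The relabeled [HmmModel-class].
#' @export
permuteStates <- function(model, perm) {
  stopifnot(identical(sort(perm), seq_len(model@K)))
  po <- model@posteriors
  pr <- model@priors
  pr$alphaPi <- pr$alphaPi[perm]
  pr$alphaA <- pr$alphaA[perm, perm, drop = FALSE]
  po$alphaPi <- po$alphaPi[perm]
  po$alphaA <- po$alphaA[perm, perm, drop = FALSE]
  po$m <- po$m[perm, , drop = FALSE]
  po$beta <- po$beta[perm]
  po$nu <- po$nu[perm]
  po$W <- po$W[perm]
  methods::new("HmmModel", K = model@K, D = model@D, priors = pr,
               posteriors = po,
               pi = model@pi[perm], A = model@A[perm, perm, drop = FALSE],
               means = model@means[perm, , drop = FALSE],
               covs = model@covs[perm])
}

# Row ranges (first, last) of each segment id in a contiguous index vector.
.segmentRanges <- function(segIdx) {
  if (!length(segIdx)) return(matrix(integer(), 0L, 2L))
  r <- rle(segIdx)
  last <- cumsum(r$lengths)
  cbind(first = c(1L, utils::head(last, -1L) + 1L), last = last)
}
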