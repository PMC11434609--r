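# Variational-Bayes Gaussian HMM.
#
# Conjugate scheme: Dirichlet priors on the initial distribution and on each
# transition row; a Normal-Wishart prior per state (Wishart on the precision
# matrix). The E-step runs scaled forward-backward under the variational
# expected parameters exp(E[log pi]), exp(E[log A]) and the expected Gaussian
# log-density; the M-step applies the conjugate count/moment updates. The
# variational free energy is the negative evidence lower bound,
#   F = -( sum_segments logZ~  -  KL(q(pi)||p) - KL(q(A)||p) - sum_k KL(q(mu_k,Lambda_k)||p) ),
# where logZ~ is the forward-pass normalizer under the expected parameters.
# F is non-increasing across iterations; for K = 1 it equals the exact
# negative log marginal likelihood of the conjugate model.

.defaultPriors <- function(X, K) {
  D <- ncol(X)
  S <- stats::cov(X)
  nu0 <- D + 1
  W0 <- .symmetrize(chol2inv(.safeChol(S * nu0, "prior scale")))
  list(alphaPi = rep(1, K), alphaA = matrix(1, K, K),
       m0 = colMeans(X), beta0 = 1, W0 = W0, nu0 = nu0)
}

# E[log det Lambda_k] under the Wishart posterior
.elogdet <- function(W, nu) {
  D <- nrow(W)
  sum(digamma((nu + 1 - seq_len(D)) / 2)) + D * log(2) + .logdet(W)
}

# Expected Gaussian log-density matrix (frames x K) under the NW posteriors.
.expectedLogDens <- function(X, model) {
  po <- model@posteriors
  K <- model@K; D <- model@D
  out <- matrix(0, nrow(X), K)
  for (k in seq_len(K)) {
    W <- po$W[[k]]
    xc <- sweep(X, 2L, po$m[k, ])
    quad <- rowSums((xc %*% W) * xc)
    out[, k] <- 0.5 * (.elogdet(W, po$nu[k]) - D * log(2 * pi) -
                         D / po$beta[k] - po$nu[k] * quad)
  }
  out
}

.expectedLogPi <- function(model) {
  a <- model@posteriors$alphaPi
  digamma(a) - digamma(sum(a))
}

.expectedLogA <- function(model) {
  a <- model@posteriors$alphaA
  digamma(a) - digamma(rowSums(a))
}

# Full E-step across segments: accumulates gamma (all frames), summed xi,
# per-segment log evidences and the summed first-frame responsibilities.
.estep <- function(X, segIdx, model) {
  logdens <- .expectedLogDens(X, model)
  lpi <- .expectedLogPi(model)
  lA <- .expectedLogA(model)
  rng <- .segmentRanges(segIdx)
  K <- model@K
  gamma <- matrix(0, nrow(X), K)
  xi <- matrix(0, K, K)
  loglik <- numeric(nrow(rng))
  gammaInit <- numeric(K)
  for (s in seq_len(nrow(rng))) {
    rows <- rng[s, 1L]:rng[s, 2L]
    fb <- fb_cpp(logdens[rows, , drop = FALSE], lpi, lA)
    gamma[rows, ] <- fb$gamma
    xi <- xi + fb$xi
    loglik[s] <- fb$logZ
    gammaInit <- gammaInit + fb$gamma[1L, ]
  }
  list(gamma = gamma, xi = xi, loglik = loglik, gammaInit = gammaInit)
}

.pointEstimates <- function(priors, po, K, D) {
  covs <- lapply(seq_len(K), function(k) {
    .symmetrize(chol2inv(.safeChol(po$W[[k]], "posterior scale")) / po$nu[k])
  })
  list(pi = po$alphaPi / sum(po$alphaPi),
       A = po$alphaA / rowSums(po$alphaA),
       means = po$m, covs = covs)
}

.mstep <- function(X, stats, priors, quiet = TRUE) {
  K <- length(stats$gammaInit); D <- ncol(X)
  gamma <- stats$gamma
  Nk <- colSums(gamma)
  empty <- which(Nk < 1e-8)
  if (length(empty) && !quiet) {
    warning("state(s) ", paste(empty, collapse = ", "),
            " have near-zero responsibility; posterior stays prior-dominated",
            call. = FALSE)
  }
  Nsafe <- pmax(Nk, 1e-10)
  xbar <- crossprod(gamma, X) / Nsafe
  W0inv <- chol2inv(.safeChol(priors$W0, "prior scale"))
  po <- list(
    alphaPi = priors$alphaPi + stats$gammaInit,
    alphaA = priors$alphaA + stats$xi,
    m = matrix(0, K, D), beta = numeric(K), nu = numeric(K), W = vector("list", K)
  )
  for (k in seq_len(K)) {
    xc <- sweep(X, 2L, xbar[k, ])
    Sk <- crossprod(xc * gamma[, k], xc) # Nk-weighted scatter (already summed)
    dm <- xbar[k, ] - priors$m0
    Winv <- W0inv + Sk +
      (priors$beta0 * Nk[k] / (priors$beta0 + Nk[k])) * tcrossprod(dm)
    po$beta[k] <- priors$beta0 + Nk[k]
    po$nu[k] <- priors$nu0 + Nk[k]
    po$m[k, ] <- (priors$beta0 * priors$m0 + Nk[k] * xbar[k, ]) / po$beta[k]
    po$W[[k]] <- .symmetrize(chol2inv(.safeChol(Winv, "posterior scale")))
  }
  pe <- .pointEstimates(priors, po, K, D)
  methods::new("HmmModel", K = as.integer(K), D = as.integer(D),
               priors = priors, posteriors = po,
               pi = pe$pi, A = pe$A, means = pe$means, covs = pe$covs)
}

.asStatePosteriors <- function(e, viterbi, segIdx) {
  methods::new("StatePosteriors", gamma = e$gamma, xi = e$xi,
               loglik = e$loglik, viterbi = as.integer(viterbi),
               segmentIndex = as.integer(segIdx))
}

.checkScores <- function(scores, segmentIndex) {
  scores <- as.matrix(scores)
  if (!nrow(scores)) stop("no frames in the data")
  if (!all(is.finite(scores))) stop("non-finite observation values")
  if (is.null(segmentIndex)) segmentIndex <- rep(1L, nrow(scores))
  if (length(segmentIndex) != nrow(scores)) {
    stop("segmentIndex length must equal the frame count")
  }
  list(X = scores, segIdx = as.integer(segmentIndex))
}

#' Initialize a variational Gaussian HMM from the data
#'
#' Priors are set from the data scale (prior mean = data mean, Wishart scale
#' matched to the data covariance, unit Dirichlet concentrations, `beta0 = 1`,
#' `nu0 = D + 1`). Responsibilities are initialized by k-means on frames with
#' the given seed and one VB M-step is applied. Deterministic given the seed.
#'
#' @param scores frames x D matrix (PCA scores).
#' @param K number of states.
#' @param seed integer seed for the k-means initialization.
#' @param segmentIndex optional per-frame contiguous segment ids.
#' @param priors optional priors list overriding the data-derived defaults.
#' @return An [HmmModel-class].
#' @export
initModel <- function(scores, K, seed = 1L, segmentIndex = NULL, priors = NULL) {
  d <- .checkScores(scores, segmentIndex)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K > nrow(d$X)) stop("K exceeds the number of frames")
  if (is.null(priors)) priors <- .defaultPriors(d$X, K)
  cl <- .withSeed(seed, {
    if (K == 1L) rep(1L, nrow(d$X)) else {
      stats::kmeans(d$X, centers = K, nstart = 3L, iter.max = 100L)$cluster
    }
  })
  gamma <- matrix(0, nrow(d$X), K)
  gamma[cbind(seq_len(nrow(d$X)), cl)] <- 1
  rng <- .segmentRanges(d$segIdx)
  xi <- matrix(0, K, K)
  gammaInit <- numeric(K)
  for (s in seq_len(nrow(rng))) {
    rows <- rng[s, 1L]:rng[s, 2L]
    gammaInit[cl[rows[1L]]] <- gammaInit[cl[rows[1L]]] + 1
    if (length(rows) > 1L) {
      from <- cl[rows[-length(rows)]]; to <- cl[rows[-1L]]
      for (i in seq_along(from)) xi[from[i], to[i]] <- xi[from[i], to[i]] + 1
    }
  }
  .mstep(d$X, list(gamma = gamma, xi = xi, gammaInit = gammaInit), priors)
}

#' Forward-backward inference for one segment
#'
#' Runs the scaled forward-backward algorithm on one contiguous segment
#' under the model's variational expected parameters. The segment is treated
#' as starting from the initial distribution; no transitions are counted
#' across segment boundaries.
#'
#' @param segmentScores frames x D matrix of one contiguous segment.
#' @param model an [HmmModel-class].
#' @return List with `gamma` (frames x K), `xi` (K x K summed pairwise
#'   expectations) and `logZ` (the segment's log-evidence contribution).
#' @export
forwardBackward <- function(segmentScores, model) {
  X <- as.matrix(segmentScores)
  if (!nrow(X)) stop("segment must contain at least one frame")
  if (!all(is.finite(X))) stop("non-finite observation values")
  if (ncol(X) != model@D) stop("observation dimension does not match the model")
  fb_cpp(.expectedLogDens(X, model), .expectedLogPi(model), .expectedLogA(model))
}

#' One conjugate VB M-step
#'
#' Updates the Dirichlet rows from the pairwise expectations and the
#' Normal-Wishart posteriors from the responsibility-weighted moments, and
#' refreshes the point estimates. A state whose total responsibility is
#' below 1e-8 keeps a prior-dominated posterior (flagged by a warning).
#'
#' @param scores frames x D matrix.
#' @param posteriors a [StatePosteriors-class] (or the list returned by
#'   [forwardBackward()] plus a `gammaInit` field).
#' @param model the current [HmmModel-class] (source of the priors).
#' @param segmentIndex optional per-frame segment ids, used to locate
#'   segment starts when `posteriors` lacks `gammaInit`.
#' @return The updated [HmmModel-class].
#' @export
vbUpdate <- function(scores, posteriors, model, segmentIndex = NULL) {
  d <- .checkScores(scores, segmentIndex)
  if (methods::is(posteriors, "StatePosteriors")) {
    rng <- .segmentRanges(if (length(posteriors@segmentIndex)) {
      posteriors@segmentIndex
    } else d$segIdx)
    gammaInit <- colSums(posteriors@gamma[rng[, 1L], , drop = FALSE])
    stats <- list(gamma = posteriors@gamma, xi = posteriors@xi,
                  gammaInit = gammaInit)
  } else {
    stats <- posteriors
  }
  .mstep(d$X, stats, model@priors, quiet = FALSE)
}

.klDirichlet <- function(a, b) {
  lgamma(sum(a)) - sum(lgamma(a)) - lgamma(sum(b)) + sum(lgamma(b)) +
    sum((a - b) * (digamma(a) - digamma(sum(a))))
}

.klNormalWishart <- function(m, beta, W, nu, m0, beta0, W0, nu0) {
  D <- length(m)
  elog <- .elogdet(W, nu)
  dm <- m - m0
  klNorm <- 0.5 * (D * beta0 / beta + beta0 * nu * sum((W %*% dm) * dm) -
                     D + D * log(beta / beta0))
  lnZ <- function(Wm, nuv) {
    (nuv * D / 2) * log(2) + (nuv / 2) * .logdet(Wm) + .lmvgamma(nuv / 2, D)
  }
  W0inv <- chol2inv(.safeChol(W0, "prior scale"))
  klWish <- ((nu - nu0) / 2) * elog - nu * D / 2 +
    (nu / 2) * sum(W0inv * W) - lnZ(W, nu) + lnZ(W0, nu0)
  klNorm + klWish
}

#' Variational free energy (negative ELBO)
#'
#' The model's alignment with the data (the summed per-segment log
#' evidences under the expected parameters) minus its complexity (the KL
#' divergences of the Dirichlet and Normal-Wishart posteriors from their
#' priors), negated. Lower is better; with posteriors equal to priors and no
#' data the free energy is exactly 0.
#'
#' @param model an [HmmModel-class].
#' @param posteriors a [StatePosteriors-class] (or list with `loglik`), or
#'   NULL for zero-length data.
#' @return Scalar free energy.
#' @export
freeEnergy <- function(model, posteriors = NULL) {
  logZ <- if (is.null(posteriors)) 0 else {
    if (methods::is(posteriors, "StatePosteriors")) sum(posteriors@loglik)
    else sum(posteriors$loglik)
  }
  pr <- model@priors; po <- model@posteriors
  kl <- .klDirichlet(po$alphaPi, pr$alphaPi)
  for (k in seq_len(model@K)) {
    kl <- kl + .klDirichlet(po$alphaA[k, ], pr$alphaA[k, ]) +
      .klNormalWishart(po$m[k, ], po$beta[k], po$W[[k]], po$nu[k],
                       pr$m0, pr$beta0, pr$W0, pr$nu0)
  }
  -(logZ - kl)
}

.viterbiPath <- function(X, segIdx, model) {
  logdens <- vapply(seq_len(model@K), function(k) {
    .logDmvnorm(X, model@means[k, ], model@covs[[k]])
  }, numeric(nrow(X)))
  logdens <- matrix(logdens, nrow(X), model@K)
  lpi <- log(model@pi)
  lA <- log(model@A)
  rng <- .segmentRanges(segIdx)
  path <- integer(nrow(X))
  for (s in seq_len(nrow(rng))) {
    rows <- rng[s, 1L]:rng[s, 2L]
    path[rows] <- viterbi_cpp(logdens[rows, , drop = FALSE], lpi, lA)
  }
  path
}

#' Fit a variational Gaussian HMM
#'
#' Alternates the forward-backward E-step and the conjugate VB M-step until
#' the relative free-energy change drops below `tol` or `maxIter` is
#' reached, over `nRestarts` k-means initializations (seeds
#' `seed, seed+1, ...`); returns the restart with the lowest final free
#' energy (ties to the lowest seed). The returned posteriors are the E-step
#' of the returned model, so re-decoding the training data reproduces them
#' exactly. Deterministic given the seed.
#'
#' @param scores frames x D matrix (PCA scores).
#' @param K number of states.
#' @param segmentIndex optional per-frame contiguous segment ids; each
#'   segment starts from the initial distribution and no transition is
#'   counted across a boundary.
#' @param maxIter maximum VB iterations (default 500).
#' @param tol relative free-energy convergence tolerance (default 1e-5).
#' @param nRestarts number of restarts (default 5).
#' @param seed master seed.
#' @param priors optional priors list.
#' @return A [FitResult-class].
#' @export
fitHmm <- function(scores, K, segmentIndex = NULL, maxIter = 500L,
                   tol = 1e-5, nRestarts = 5L, seed = 1L, priors = NULL) {
  d <- .checkScores(scores, segmentIndex)
  if (is.null(priors)) priors <- .defaultPriors(d$X, as.integer(K))
  best <- NULL
  for (r in seq_len(nRestarts)) {
    rseed <- as.integer(seed) + r - 1L
    model <- initModel(d$X, K, seed = rseed, segmentIndex = d$segIdx,
                       priors = priors)
    trace <- numeric(0)
    converged <- FALSE
    e <- NULL
    for (it in seq_len(maxIter)) {
      e <- .estep(d$X, d$segIdx, model)
      fe <- freeEnergy(model, e)
      trace <- c(trace, fe)
      if (it > 1L &&
          abs(trace[it - 1L] - fe) < tol * max(1, abs(trace[it - 1L]))) {
        converged <- TRUE
        break
      }
      if (it == maxIter) break
      model <- .mstep(d$X, e, priors)
    }
    if (!converged) {
      warning("restart ", r, " did not converge in ", maxIter, " iterations",
              call. = FALSE)
    }
    fe <- trace[length(trace)]
    if (is.null(best) || fe < best$fe) {
      best <- list(model = model, e = e, trace = trace, fe = fe,
                   converged = converged, seed = rseed)
    }
  }
  vit <- .viterbiPath(d$X, d$segIdx, best$model)
  methods::new("FitResult",
               model = best$model,
               posteriors = .asStatePosteriors(best$e, vit, d$segIdx),
               freeEnergyTrace = best$trace,
               converged = best$converged,
               seed = best$seed,
               nRestartsUsed = as.integer(nRestarts))
}

#' Decode state time courses
#'
#' `mode = "posterior"` fills per-frame state probabilities (gamma) from the
#' forward-backward pass under the variational expected parameters;
#' `mode = "viterbi"` additionally guarantees the exact most-probable path
#' under the point estimates (computed in either mode; segments decoded
#' independently).
#'
#' @param scores frames x D matrix.
#' @param model a fitted [HmmModel-class].
#' @param segmentIndex optional per-frame segment ids.
#' @param mode `"posterior"` or `"viterbi"`.
#' @return A [StatePosteriors-class] (gamma, xi, per-segment log evidence,
#'   Viterbi path).
#' @export
decodeStates <- function(scores, model, segmentIndex = NULL,
                         mode = c("posterior", "viterbi")) {
  mode <- match.arg(mode)
  d <- .checkScores(scores, segmentIndex)
  if (ncol(d$X) != model@D) stop("observation dimension does not match the model")
  e <- .estep(d$X, d$segIdx, model)
  vit <- .viterbiPath(d$X, d$segIdx, model)
  .asStatePosteriors(e, vit, d$segIdx)
}

#' Apply a frozen model to new data (semi-supervised generalization)
#'
#' Emission and transition parameters stay fixed at their trained
#' posteriors; only the state time courses of the new recording are
#' inferred (one E-step plus a Viterbi pass). The new data must have been
#' standardized and projected through the same PCA model as the training
#' night.
#'
#' @param newScores frames x D matrix from the held-out recording.
#' @param model the trained [HmmModel-class].
#' @param segmentIndex optional per-frame segment ids.
#' @return A [StatePosteriors-class] for the new recording.
#' @export
applyModel <- function(newScores, model, segmentIndex = NULL) {
  if (!length(newScores)) stop("new data is empty")
  d <- .checkScores(newScores, segmentIndex)
  if (ncol(d$X) != model@D) {
    stop("PCA dimension mismatch: data has ", ncol(d$X),
         " components, model expects ", model@D)
  }
  decodeStates(d$X, model, d$segIdx)
}
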