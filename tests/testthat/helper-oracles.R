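# Independent oracles and fixture builders. Everything here is deliberately
# naive (enumeration, sequential closed forms) and never calls the code paths
# it is used to check.

# Exhaustive-path oracle for forward-backward quantities: enumerates all K^T
# state paths and accumulates exact posterior marginals and the evidence.
bruteForceFB <- function(logdens, logpi, logA) {
  T <- nrow(logdens); K <- ncol(logdens)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  lw <- apply(paths, 1L, function(p) {
    s <- logpi[p[1L]] + logdens[1L, p[1L]]
    if (T > 1L) for (t in 2:T) s <- s + logA[p[t - 1L], p[t]] + logdens[t, p[t]]
    s
  })
  logZ <- max(lw) + log(sum(exp(lw - max(lw))))
  w <- exp(lw - logZ)
  gamma <- matrix(0, T, K); xi <- matrix(0, K, K)
  for (i in seq_len(nrow(paths))) {
    p <- paths[i, ]
    for (t in seq_len(T)) gamma[t, p[t]] <- gamma[t, p[t]] + w[i]
    if (T > 1L) for (t in seq_len(T - 1L)) {
      xi[p[t], p[t + 1L]] <- xi[p[t], p[t + 1L]] + w[i]
    }
  }
  list(gamma = gamma, xi = xi, logZ = logZ,
       viterbi = as.integer(paths[which.max(lw), ]))
}

# Exact log marginal likelihood of the one-state Normal-Wishart conjugate
# model, via the product of sequential multivariate Student-t posterior
# predictives (a route entirely different from the variational bound).
logMvt <- function(x, mu, Sigma, df) {
  D <- length(x)
  ch <- chol(Sigma)
  q <- sum(backsolve(ch, x - mu, transpose = TRUE)^2)
  lgamma((df + D) / 2) - lgamma(df / 2) - (D / 2) * log(df * pi) -
    sum(log(diag(ch))) - ((df + D) / 2) * log1p(q / df)
}

normalWishartEvidence <- function(X, m0, beta0, W0, nu0) {
  D <- ncol(X)
  m <- m0; beta <- beta0; nu <- nu0; Winv <- solve(W0)
  ll <- 0
  for (t in seq_len(nrow(X))) {
    x <- X[t, ]
    df <- nu - D + 1
    ll <- ll + logMvt(x, m, Winv * (beta + 1) / (beta * df), df)
    Winv <- Winv + (beta / (beta + 1)) * tcrossprod(x - m)
    m <- (beta * m + x) / (beta + 1)
    beta <- beta + 1; nu <- nu + 1
  }
  ll
}

# All set partitions of 1..n as restricted growth strings (Bell(8) = 4140).
allSetPartitions <- function(n) {
  out <- list()
  rec <- function(s, m) {
    if (length(s) == n) { out[[length(out) + 1L]] <<- s; return(invisible()) }
    for (v in seq_len(m + 1L)) rec(c(s, v), max(m, v))
  }
  rec(1L, 1L)
  out
}

directedQOracle <- function(W, assignment) {
  m <- sum(W)
  B <- W - outer(rowSums(W), colSums(W)) / m
  sum(B[outer(assignment, assignment, "==")]) / m
}

# Planted-module transition matrix: within:between off-diagonal mass ratio.
plantedModuleMatrix <- function(K = 21L, nModules = 5L, ratio = 9, seed = 1L) {
  withr::with_seed(seed, {
    truth <- sort(rep_len(seq_len(nModules), K))
    W <- matrix(stats::runif(K * K, 0.5, 1.5), K, K)
    same <- outer(truth, truth, "==")
    W[!same] <- W[!same] / ratio
    diag(W) <- 0
    list(W = W / rowSums(W), truth = truth)
  })
}

# Markov-path recovery fixture: shared stage pools make the planted path a
# single Markov chain with transition matrix A.
makeRecoveryFixture <- function(nParticipants = 3L, nFrames = 2000L,
                                K = 6L, R = 20L, nComponents = 13L,
                                seed = 11L) {
  model <- defaultGenerativeModel(K = K, R = R, seed = 1L, pools = "shared")
  spec <- hypnogramSpec(data.frame(stage = "Wake", meanDwell = nFrames),
                        nCycles = 1L, trSeconds = 3, dwellDispersion = 0)
  ds <- simulateSleepDataset(nParticipants, model, spec, seed = seed)
  sessions <- lapply(ds@sessions, standardize)
  concat <- concatenateSessions(sessions)
  pca <- fitPca(concat, nComponents)
  # true state means mapped into score space via pooled standardization
  raw <- do.call(rbind, lapply(ds@sessions, function(s) s@data))
  mu <- colMeans(raw); sdv <- apply(raw, 2L, stats::sd)
  trueStd <- sweep(sweep(stateMeans(model), 2L, mu), 2L, sdv, "/")
  trueScores <- sweep(trueStd, 2L, pca$model@channelMeans) %*% pca$model@mixing
  list(ds = ds, model = model, concat = concat, pca = pca,
       trueScores = trueScores)
}

# A small arbitrary fitted-model stand-in with given point parameters and
# sharply concentrated posteriors, for decode-level tests against the truth.
randomVbModel <- function(K, D, seed = 1L, T = 60L) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(T * D), T, D)
  })
  suppressWarnings(fitHmm(X, K, nRestarts = 1L, maxIter = 10L, seed = seed))@model
}
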