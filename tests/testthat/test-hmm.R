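test_that("forward-backward matches exhaustive path enumeration", {
  withr::with_seed(101, {
    for (rep in 1:20) {
      T <- sample(2:6, 1L); K <- sample(2:3, 1L)
      logdens <- matrix(rnorm(T * K), T, K)
      lpi <- log(runif(K)); lA <- matrix(log(runif(K * K)), K, K)
      fb <- sleepHMM:::fb_cpp(logdens, lpi, lA)
      bf <- bruteForceFB(logdens, lpi, lA)
      expect_lt(max(abs(fb$gamma - bf$gamma)), 1e-10)
      expect_lt(max(abs(fb$xi - bf$xi)), 1e-10)
      expect_lt(abs(fb$logZ - bf$logZ), 1e-10)
      vit <- sleepHMM:::viterbi_cpp(logdens, lpi, lA)
      expect_identical(as.integer(vit), bf$viterbi)
    }
  })
})

test_that("forward-backward degenerate cases behave", {
  # K = 1: gamma is identically 1 and logZ the summed log-density
  logdens <- matrix(c(-1.5, -2, -0.3), 3L, 1L)
  fb <- sleepHMM:::fb_cpp(logdens, 0, matrix(0, 1L, 1L))
  expect_equal(as.numeric(fb$gamma), rep(1, 3L))
  expect_equal(fb$logZ, sum(logdens))

  # identical emissions + uniform pi and A: gamma is 1/K by symmetry
  K <- 3L
  logdens <- matrix(rep(c(-1, -2, -3, -1), each = K), 4L, K, byrow = TRUE)
  fb <- sleepHMM:::fb_cpp(logdens, log(rep(1 / K, K)),
                          matrix(log(1 / K), K, K))
  expect_equal(fb$gamma, matrix(1 / K, 4L, K), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(forwardBackward(matrix(NaN, 2L, 2L), randomVbModel(2L, 2L)),
               "non-finite")
})

test_that("initialization is deterministic and finds separated clusters", {
  withr::with_seed(5, {
    centers <- matrix(c(0, 0, 6, 6, -6, 6), 3L, 2L, byrow = TRUE)
    X <- centers[rep(1:3, each = 60L), ] + matrix(rnorm(360, sd = 0.3), 180L, 2L)
  })
  m1 <- initModel(X, 3L, seed = 2L)
  m2 <- initModel(X, 3L, seed = 2L)
  expect_identical(m1@means, m2@means)
  expect_identical(m1@posteriors$alphaA, m2@posteriors$alphaA)

  # initial means near the k-means centers (within 0.5 after matching)
  perm <- matchStates(m1@means, centers)
  expect_lt(max(abs(m1@means[perm, ] - centers)), 0.5)

  expect_error(initModel(X, 200L, seed = 1L), "frames")

  # K = 1: single state mean equals the data mean (up to the weak prior)
  m0 <- initModel(X, 1L, seed = 1L)
  expect_equal(as.numeric(m0@means), colMeans(X), tolerance = 0.05)
})

test_that("vb update recovers weighted moments in the weak-prior limit", {
  withr::with_seed(6, X <- matrix(rnorm(80), 40L, 2L) + 3)
  K <- 2L
  priors <- sleepHMM:::.defaultPriors(X, K)
  priors$beta0 <- 1e-8
  gamma <- cbind(rep(1, 40L), rep(0, 40L)) # one-hot to state 1
  stats <- list(gamma = gamma, xi = matrix(c(39, 0, 0, 0), 2L, 2L),
                gammaInit = c(1, 0))
  m <- sleepHMM:::.mstep(X, stats, priors)
  expect_equal(as.numeric(m@means[1L, ]), colMeans(X), tolerance = 1e-6)

  # row-stochasticity preserved by every update
  expect_lt(max(abs(rowSums(m@A) - 1)), 1e-10)
})

test_that("free energy is exact for the conjugate one-state model", {
  withr::with_seed(7, {
    X <- matrix(rnorm(120), 40L, 3L) %*%
      matrix(c(1, .3, 0, .3, 1, .2, 0, .2, 1), 3L)
  })
  fit <- fitHmm(X, 1L, nRestarts = 1L, seed = 3L)
  fe <- tail(freeEnergyTrace(fit), 1L)
  pr <- hmmModel(fit)@priors
  ev <- normalWishartEvidence(X, pr$m0, pr$beta0, pr$W0, pr$nu0)
  expect_equal(fe, -ev, tolerance = 1e-6)
})

test_that("free energy is zero for prior-only posteriors and no data", {
  m <- randomVbModel(2L, 2L, seed = 9L)
  m@posteriors <- c(m@priors[c("alphaPi", "alphaA")],
                    list(m = rbind(m@priors$m0, m@priors$m0),
                         beta = rep(m@priors$beta0, 2L),
                         W = rep(list(m@priors$W0), 2L),
                         nu = rep(m@priors$nu0, 2L)))
  expect_equal(freeEnergy(m, NULL), 0, tolerance = 1e-10)
})

test_that("free energy is non-increasing on random fixtures", {
  withr::with_seed(8, {
    for (rep in 1:20) {
      T <- 80L; D <- 2L; K <- sample(2:3, 1L)
      X <- matrix(rnorm(T * D), T, D) +
        matrix(rnorm(K * D, sd = 2), K, D)[sample.int(K, T, TRUE), ]
      fit <- suppressWarnings(
        fitHmm(X, K, nRestarts = 1L, maxIter = 60L, seed = rep))
      tr <- freeEnergyTrace(fit)
      expect_true(all(diff(tr) <= 1e-8 * pmax(1, abs(tr[-length(tr)]))))
    }
  })
})

test_that("free energy is invariant under state relabeling", {
  withr::with_seed(10, X <- matrix(rnorm(200), 100L, 2L))
  fit <- suppressWarnings(fitHmm(X, 3L, nRestarts = 1L, maxIter = 30L, seed = 1L))
  e <- sleepHMM:::.estep(X, rep(1L, 100L), hmmModel(fit))
  f0 <- freeEnergy(hmmModel(fit), e)
  perm <- c(3L, 1L, 2L)
  mp <- permuteStates(hmmModel(fit), perm)
  ep <- sleepHMM:::.estep(X, rep(1L, 100L), mp)
  expect_equal(freeEnergy(mp, ep), f0, tolerance = 1e-10)
  # gamma rows stay normalized under the permuted model
  expect_lt(max(abs(rowSums(ep$gamma) - 1)), 1e-8)
})

test_that("fitting recovers a planted three-state model", {
  withr::with_seed(12, {
    A <- matrix(c(.8, .1, .1, .15, .8, .05, .1, .1, .8), 3L, byrow = TRUE)
    means <- matrix(c(0, 0, 4, 4, -4, 4), 3L, 2L, byrow = TRUE)
    path <- integer(4000L); path[1L] <- 1L
    for (t in 2:4000) path[t] <- sample.int(3L, 1L, prob = A[path[t - 1L], ])
    X <- means[path, ] + matrix(rnorm(8000), 4000L, 2L)
  })
  fit <- fitHmm(X, 3L, nRestarts = 3L, seed = 4L)
  perm <- matchStates(stateMeans(fit), means)
  expect_lt(max(abs(stateMeans(fit)[perm, ] - means)), 0.1)
  expect_lt(max(abs(transitionMatrix(fit)[perm, perm] - A)), 0.05)
})

test_that("viterbi decoding is exact and consistent with gamma", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      T <- 5L; K <- 2L
      logdens <- matrix(rnorm(T * K), T, K)
      lpi <- log(c(.4, .6)); lA <- log(matrix(c(.7, .3, .2, .8), 2L, byrow = TRUE))
      vit <- sleepHMM:::viterbi_cpp(logdens, lpi, lA)
      bf <- bruteForceFB(logdens, lpi, lA)
      expect_identical(as.integer(vit), bf$viterbi)
    }
  })
  # near-deterministic emissions: viterbi equals the generating path
  model <- defaultGenerativeModel(separation = 6)
  ds <- simulateSleepDataset(1L, model, defaultHypnogramSpec(nCycles = 10L),
                             seed = 3L)
  X <- ds@sessions[[1L]]@data
  fit <- fitHmm(X, 6L, nRestarts = 3L, seed = 2L)
  perm <- matchStates(stateMeans(fit), stateMeans(model))
  relabeled <- order(perm)[viterbiPath(fit)] # inverse permutation
  expect_gt(mean(relabeled == ds@truePath[[1L]]), 0.98)
  # argmax of gamma agrees with viterbi on nearly every frame
  gmax <- max.col(stateProbabilities(fit), ties.method = "first")
  expect_gt(mean(gmax == viterbiPath(fit)), 0.95)
})

test_that("a frozen model applied to its training data reproduces the fit", {
  withr::with_seed(14, X <- matrix(rnorm(300), 150L, 2L))
  fit <- suppressWarnings(fitHmm(X, 2L, nRestarts = 1L, maxIter = 40L, seed = 6L))
  post <- applyModel(X, hmmModel(fit))
  expect_equal(stateProbabilities(post), stateProbabilities(fit),
               tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(sum(post@loglik), sum(fit@posteriors@loglik), tolerance = 1e-8)

  expect_error(applyModel(matrix(0, 0L, 2L), hmmModel(fit)), "empty|frames")
  expect_error(applyModel(matrix(0, 5L, 3L), hmmModel(fit)), "dimension")
})

test_that("segments are inferred independently", {
  # two segments: each restarts from pi; xi counts no cross-boundary pair
  withr::with_seed(15, X <- matrix(rnorm(40), 20L, 2L))
  segIdx <- rep(1:2, each = 10L)
  fit <- suppressWarnings(
    fitHmm(X, 2L, segmentIndex = segIdx, nRestarts = 1L, maxIter = 20L, seed = 1L))
  e <- sleepHMM:::.estep(X, segIdx, hmmModel(fit))
  expect_equal(sum(e$xi), 18, tolerance = 1e-8) # (10-1) pairs per segment
  expect_length(e$loglik, 2L)
})
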