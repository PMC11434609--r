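test_that("hypnogram simulation honours the cycle template", {
  # degenerate dwell: dispersion 0 gives exactly the template
  spec <- hypnogramSpec(data.frame(stage = "Wake", meanDwell = 10),
                        nCycles = 1L, dwellDispersion = 0)
  expect_identical(simulateHypnogram(spec, seed = 1L), rep("Wake", 10L))

  # bout order forced by the template across cycles
  spec2 <- hypnogramSpec(data.frame(stage = c("N2", "N3"), meanDwell = c(20, 20)),
                         nCycles = 2L, dwellDispersion = 0)
  hyp <- simulateHypnogram(spec2, seed = 1L)
  r <- rle(hyp)
  expect_identical(r$values, c("N2", "N3", "N2", "N3"))
  expect_length(hyp, 80L)

  # sampled dwells hit the stated mean (200 bouts of mean 100)
  spec3 <- hypnogramSpec(data.frame(stage = "N2", meanDwell = 100),
                         nCycles = 200L, dwellDispersion = 0.3)
  lens <- rle(c(simulateHypnogram(spec3, seed = 7L)))$lengths
  # bouts of the same stage merge in rle; total frames / 200 is the mean dwell
  expect_equal(sum(lens) / 200, 100, tolerance = 0.1)

  expect_error(hypnogramSpec(data.frame(stage = "Wake", meanDwell = 0)),
               "dwell")
  expect_error(hypnogramSpec(data.frame(stage = "N4", meanDwell = 5)),
               "stage")
})

test_that("state sequences nest within stage pools", {
  model <- defaultGenerativeModel() # singleton pools
  hyp <- simulateHypnogram(defaultHypnogramSpec(nCycles = 3L), seed = 2L)
  path <- simulateStateSequence(hyp, model, seed = 3L)
  # singleton pools: the path is a deterministic relabeling of the hypnogram
  expect_identical(path, match(hyp, sleepStages()))

  # empty pool for an occurring stage is a configuration error
  m2 <- model
  m2@stagePools$REM <- integer(0)
  expect_error(simulateStateSequence(hyp, m2, seed = 1L), "empty state pool")
})

test_that("within-pool dwells follow the geometric law 1/(1-p)", {
  model <- defaultGenerativeModel(pools = "shared", selfTransition = 0.9)
  hyp <- rep("Wake", 20000L)
  path <- simulateStateSequence(hyp, model, seed = 5L)
  meanDwell <- mean(rle(path)$lengths)
  expect_equal(meanDwell, 1 / (1 - 0.9), tolerance = 0.1)
})

test_that("emissions are state-specific Gaussians", {
  K <- 3L; R <- 4L
  means <- matrix(seq_len(K * R), K, R)
  eps <- diag(1e-12, R)
  model <- methods::new("GenerativeModel", K = K, R = R,
                        stagePools = list(Wake = 1:3), A = diag(K),
                        pi = c(1, 0, 0), means = means,
                        covs = rep(list(eps), K))
  path <- c(1L, 2L, 3L, 2L)
  obs <- simulateObservations(path, model, seed = 1L)
  expect_equal(obs@data, means[path, ], tolerance = 1e-5,
               ignore_attr = TRUE)

  # CLT bound on the sample mean, K = 1, mean 0, cov I
  m1 <- methods::new("GenerativeModel", K = 1L, R = R,
                     stagePools = list(Wake = 1L), A = matrix(1),
                     pi = 1, means = matrix(0, 1L, R),
                     covs = list(diag(R)))
  X <- simulateObservations(rep(1L, 10000L), m1, seed = 2L)@data
  expect_true(all(abs(colMeans(X)) < 0.05))

  # per-state sample covariance converges to the planted covariance
  model6 <- defaultGenerativeModel()
  X6 <- simulateObservations(rep(3L, 5000L), model6, seed = 3L)@data
  S <- stats::cov(X6)
  relErr <- norm(S - model6@covs[[3L]], "F") / norm(model6@covs[[3L]], "F")
  expect_lt(relErr, 0.1)

  badCov <- matrix(c(1, 2, 2, 1), 2L)
  expect_error(methods::new("GenerativeModel", K = 1L, R = 2L,
                            stagePools = list(Wake = 1L), A = matrix(1),
                            pi = 1, means = matrix(0, 1L, 2L),
                            covs = list(badCov)),
               "positive-definite")
})

test_that("identical seeds give bit-identical datasets", {
  a <- simulateSleepDataset(2L, spec = defaultHypnogramSpec(nCycles = 4L),
                            seed = 9L)
  b <- simulateSleepDataset(2L, spec = defaultHypnogramSpec(nCycles = 4L),
                            seed = 9L)
  expect_identical(lapply(a@sessions, function(s) s@data),
                   lapply(b@sessions, function(s) s@data))
  expect_identical(a@truePath, b@truePath)
  expect_identical(a@hypnogram, b@hypnogram)
})

test_that("planted stage-state nesting is recoverable from the true path", {
  ds <- simulateSleepDataset(1L, spec = defaultHypnogramSpec(nCycles = 20L),
                             seed = 4L)
  sd6 <- stageDistribution(ds@truePath[[1L]], ds@hypnogram[[1L]], K = 6L)
  # each state's modal stage is its singleton pool's stage
  expect_identical(winnerTakesAll(sd6), sleepStages())
})

test_that("datasets round-trip through disk losslessly", {
  ds <- simulateSleepDataset(2L, spec = defaultHypnogramSpec(nCycles = 3L),
                             seed = 6L)
  dir <- withr::local_tempdir()
  writeDataset(ds, dir)
  back <- readDataset(dir)
  for (i in 1:2) {
    expect_equal(back@sessions[[i]]@data, ds@sessions[[i]]@data,
                 tolerance = 1e-12)
  }
  expect_identical(back@truePath, ds@truePath)
  expect_identical(back@hypnogram, ds@hypnogram)
  expect_equal(back@model@A, ds@model@A, tolerance = 1e-12)
  expect_equal(back@model@means, ds@model@means, tolerance = 1e-12)
})
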