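test_that("off-diagonal normalization removes self-transition mass", {
  A <- matrix(c(0.9, 0.1, 0.2, 0.8), 2L, byrow = TRUE)
  expect_equal(offDiagonalNormalize(A),
               matrix(c(0, 1, 1, 0), 2L, byrow = TRUE))
  expect_warning(z <- offDiagonalNormalize(diag(2L)), "zero rows")
  expect_equal(z, matrix(0, 2L, 2L))
  W <- matrix(c(0, 0.6, 0.4, 0.3, 0, 0.7, 0.5, 0.5, 0), 3L, byrow = TRUE)
  expect_equal(offDiagonalNormalize(W), W,
               tolerance = 1e-12) # already zero-diagonal stochastic rows
  expect_error(offDiagonalNormalize(matrix(1)), "two states")
})

test_that("block-diagonal transition graphs split exactly into their blocks", {
  Wb <- matrix(0, 6L, 6L)
  Wb[1:3, 1:3] <- 0.5; Wb[4:6, 4:6] <- 0.5; diag(Wb) <- 0
  Wb <- Wb / rowSums(Wb)
  part <- directedModularity(Wb)
  expect_identical(part@nModules, 2L)
  expect_identical(part@assignment[1:3], rep(part@assignment[1L], 3L))
  expect_identical(part@assignment[4:6], rep(part@assignment[4L], 3L))
  # Q equals the exhaustive-search maximum over all partitions
  qs <- vapply(allSetPartitions(6L), function(a) directedQOracle(Wb, a), 0)
  expect_equal(modularityScore(part), max(qs), tolerance = 1e-9)
})

test_that("uniform graphs stay a single module with Q near zero", {
  Wu <- matrix(1 / 5, 6L, 6L); diag(Wu) <- 0
  part <- directedModularity(Wu)
  expect_identical(part@nModules, 1L)
  expect_lt(abs(modularityScore(part)), 1e-10)
  # any split of a uniform graph scores <= 0
  qs <- vapply(allSetPartitions(6L), function(a) directedQOracle(Wu, a), 0)
  expect_lte(max(qs), 1e-12)
})

test_that("spectral partitions reach the brute-force optimum on small graphs", {
  withr::with_seed(21, {
    for (rep in 1:20) {
      K <- sample(4:7, 1L)
      W <- matrix(runif(K * K), K, K); diag(W) <- 0
      part <- directedModularity(W)
      qs <- vapply(allSetPartitions(K), function(a) directedQOracle(W, a), 0)
      qbest <- max(qs)
      expect_gte(modularityScore(part) + 1e-9,
                 if (qbest > 0) 0.95 * qbest else qbest)
      # never worse than the single-module partition (Q = 0)
      expect_gte(modularityScore(part), -1e-12)
    }
  })
})

test_that("planted five-module structure is recovered perfectly", {
  p <- plantedModuleMatrix(K = 21L, nModules = 5L, ratio = 9, seed = 1L)
  part <- directedModularity(p$W)
  expect_identical(part@nModules, 5L)
  expect_equal(mclust::adjustedRandIndex(moduleAssignment(part), p$truth), 1)
})

test_that("Q is invariant under state and module relabeling", {
  p <- plantedModuleMatrix(K = 12L, nModules = 3L, seed = 2L)
  part <- directedModularity(p$W)
  perm <- withr::with_seed(3, sample(12L))
  partP <- directedModularity(p$W[perm, perm])
  expect_equal(modularityScore(partP), modularityScore(part),
               tolerance = 1e-10)
  expect_identical(partP@nModules, part@nModules)

  expect_error(directedModularity(matrix(0, 3L, 3L)), "mass")
  expect_error(directedModularity(matrix(-1, 3L, 3L)), "nonnegative")
})

test_that("module stage profiles are occupancy-weighted and normalized", {
  sd6 <- rbind(c(1, 0, 0, 0, 0, 0),
               c(0, 0, 1, 0, 0, 0),
               c(0, 0, 1, 0, 0, 0))
  colnames(sd6) <- sleepStages()
  part <- methods::new("ModulePartition", assignment = c(1L, 2L, 2L),
                       q = 0.1, nModules = 2L)
  prof <- moduleStageProfile(part, sd6, fo = c(0.2, 0.3, 0.5))
  expect_equal(unname(prof[1L, ]), c(1, 0, 0, 0, 0, 0)) # single-state module
  expect_equal(unname(prof[2L, 3L]), 1) # identical rows stay that row
  expect_equal(rowSums(prof), c(module1 = 1, module2 = 1))
})
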