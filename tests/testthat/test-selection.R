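test_that("first local minimum follows the curve-reading rule", {
  expect_identical(firstLocalMinimum(c(5, 4, 3, 3.5, 2), 2:6), 4L)
  # strictly decreasing: global argmin fallback (last K)
  expect_identical(firstLocalMinimum(c(5, 4, 3, 2, 1), 2:6), 6L)
  # plateau: tie breaks toward the smaller K
  expect_identical(firstLocalMinimum(c(3, 1, 1, 2), 1:4), 2L)
  expect_error(firstLocalMinimum(c(1, 2), 1:2), "three")
})

test_that("fractional occupancy statistics summarize gamma columns", {
  g <- matrix(0.5, 10L, 2L)
  fos <- fractionalOccupancyStats(g)
  expect_equal(unname(fos), c(0.5, 0.5))

  g3 <- matrix(0, 8L, 3L); g3[, 1L] <- 1
  fos3 <- fractionalOccupancyStats(g3)
  expect_equal(unname(fos3["maxFo"]), 1)
  expect_equal(unname(fos3["medianFo"]), 0)

  withr::with_seed(2, gr <- matrix(runif(60), 20L, 3L))
  gr <- gr / rowSums(gr)
  expect_equal(sum(colMeans(gr)), 1, tolerance = 1e-8)
  expect_error(fractionalOccupancyStats(matrix(0, 0L, 2L)), "empty")
})

test_that("Wilks' lambda matches the direct scatter-matrix formula", {
  withr::with_seed(3, {
    gamma <- matrix(runif(300), 100L, 3L)
    gamma <- gamma / rowSums(gamma)
    groups <- rep(c("Wake", "N2"), each = 50L)
  })
  lam <- wilksLambda(gamma, groups)
  # oracle: direct det(W)/det(T) on the rank-repaired columns
  X <- gamma[, -3L]
  Tm <- crossprod(scale(X, scale = FALSE))
  W <- crossprod(scale(X[1:50, ], scale = FALSE)) +
    crossprod(scale(X[51:100, ], scale = FALSE))
  expect_equal(lam, det(W) / det(Tm), tolerance = 1e-10)
  expect_gt(lam, 0); expect_lte(lam, 1)

  # identical group means: lambda = 1
  g2 <- rbind(c(.6, .4), c(.2, .8), c(.6, .4), c(.2, .8))
  expect_equal(wilksLambda(g2, c("Wake", "Wake", "N2", "N2")), 1,
               tolerance = 1e-10)

  # complete separation: lambda near 0
  g3 <- rbind(matrix(rep(c(1, 0), 30L), 30L, 2L, byrow = TRUE) +
                cbind(rnorm(30L, sd = 1e-3), 0),
              matrix(rep(c(0, 1), 30L), 30L, 2L, byrow = TRUE) +
                cbind(rnorm(30L, sd = 1e-3), 0))
  g3 <- pmin(pmax(g3, 0), 1); g3 <- g3 / rowSums(g3)
  expect_lt(wilksLambda(g3, rep(c("Wake", "N3"), each = 30L)), 1e-3)

  # invariance under state-index permutation
  lamPerm <- wilksLambda(gamma[, c(2L, 3L, 1L)], groups)
  expect_equal(lamPerm, lam, tolerance = 1e-8)

  expect_error(wilksLambda(gamma, rep("Wake", 100L)), "two")
})

test_that("order scans record aligned statistics and choose K", {
  withr::with_seed(4, {
    means <- matrix(c(0, 0, 5, 5), 2L, 2L, byrow = TRUE)
    path <- sample.int(2L, 400L, TRUE)
    X <- means[path, ] + matrix(rnorm(800), 400L, 2L)
  })
  scan <- suppressWarnings(
    scanOrders(X, 2:4, trSeconds = 3, seed = 1L, nRestarts = 1L,
               maxIter = 60L))
  expect_length(scan@freeEnergies, 3L)
  expect_true(all(is.finite(scan@freeEnergies)))
  expect_true(chosenK(scan) %in% 2:4)
  df <- as.data.frame(scan)
  expect_identical(df$k, 2:4)

  expect_error(scanOrders(X, c(4L, 2L)), "ascending")
})

test_that("max fractional occupancy declines then stabilizes with K", {
  ds <- simulateSleepDataset(1L, spec = defaultHypnogramSpec(nCycles = 12L),
                             seed = 5L)
  X <- standardize(ds@sessions[[1L]])@data
  scan <- suppressWarnings(
    scanOrders(X, c(2L, 4L, 6L, 8L), trSeconds = 3, seed = 2L,
               nRestarts = 1L, maxIter = 80L))
  # smoothed trend: max FO at high K is no larger than at K = 2
  expect_lte(scan@maxFo[4L], scan@maxFo[1L] + 1e-8)
  expect_true(all(diff(scan@maxFo) <= 0.15)) # no substantial rebound
})
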