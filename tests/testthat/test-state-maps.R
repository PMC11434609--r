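test_that("back-projection reduces to the identity when mixing is identity", {
  model <- suppressWarnings(
    fitHmm(withr::with_seed(1, matrix(rnorm(200), 100L, 2L)), 2L,
           nRestarts = 1L, maxIter = 20L, seed = 1L))@model
  pca <- methods::new("PcaModel", mixing = diag(2L),
                      componentVariances = c(2, 1), totalVariance = 3,
                      nComponents = 2L, channelMeans = c(0, 0))
  proj <- projectToRoi(model, pca)
  expect_equal(proj$means, model@means, tolerance = 1e-12)
  expect_equal(proj$covs[[1L]], model@covs[[1L]], tolerance = 1e-12)

  # zero state mean in component space maps to the channel means
  m0 <- model; m0@means <- matrix(0, 2L, 2L)
  pca2 <- pca; pca2@channelMeans <- c(5, -3)
  expect_equal(projectToRoi(m0, pca2)$means,
               matrix(c(5, -3), 2L, 2L, byrow = TRUE), tolerance = 1e-12)

  pca3 <- methods::new("PcaModel", mixing = matrix(1, 3L, 1L) / sqrt(3),
                       componentVariances = 1, totalVariance = 2,
                       nComponents = 1L, channelMeans = rep(0, 3L))
  expect_error(projectToRoi(model, pca3), "does not match")
})

test_that("round-tripping a mean through the component subspace is a projection", {
  withr::with_seed(2, {
    X <- matrix(rnorm(500 * 8), 500L, 8L)
    v <- rnorm(8L)
  })
  fp <- fitPca(X, 4L)
  M <- fp$model@mixing
  # project the vector into component space and back: equals its orthogonal
  # projection onto the component subspace
  back <- as.numeric(M %*% (t(M) %*% v))
  expect_equal(back, as.numeric(M %*% t(M) %*% v), tolerance = 1e-12)
  expect_lt(max(abs(t(M) %*% (v - back))), 1e-10) # residual orthogonal

  # projected state covariances stay PSD up to numerical floor
  S <- crossprod(matrix(rnorm(16), 4L)) + diag(4L)
  roiCov <- M %*% S %*% t(M)
  expect_gt(min(eigen(roiCov, symmetric = TRUE)$values), -1e-8)
})

test_that("relative activation centers across states", {
  m <- rbind(c(1, 2), c(3, 6), c(5, 4))
  rel <- relativeActivation(m)
  expect_equal(colSums(rel), c(0, 0), tolerance = 1e-10)
  expect_equal(relativeActivation(rel), rel, tolerance = 1e-12) # idempotent
  expect_equal(relativeActivation(rbind(c(1, 1), c(1, 1))),
               matrix(0, 2L, 2L), tolerance = 1e-12)
  pm <- rbind(c(2, -1), c(-2, 1))
  expect_equal(relativeActivation(pm), pm, tolerance = 1e-12) # +/- v stays
})

test_that("state FC normalizes covariance to correlation", {
  expect_equal(stateFc(diag(c(2, 3, 4))), diag(3L), tolerance = 1e-12)
  v <- c(1, 2, 3)
  expect_equal(stateFc(tcrossprod(v)), matrix(1, 3L, 3L), tolerance = 1e-12)
  withr::with_seed(3, S <- crossprod(matrix(rnorm(36), 6L)) + diag(6L))
  fc <- stateFc(S)
  oracle <- S / sqrt(outer(diag(S), diag(S)))
  expect_equal(fc, oracle, tolerance = 1e-12)
  expect_error(stateFc(diag(c(-1, 1))), "negative variance")
  Sz <- diag(c(0, 1, 1))
  expect_warning(fz <- stateFc(Sz), "zero-variance")
  expect_true(all(is.na(fz[1L, ])))
})

test_that("network aggregation averages Fisher-z over blocks", {
  nets <- c("A", "A", "B", "B")
  fc0 <- diag(4L) # all off-diagonal r = 0
  agg0 <- networkAggregate(fc0, nets)
  expect_equal(unname(as.vector(agg0)), rep(0, 4L))

  fc5 <- matrix(0.5, 4L, 4L); diag(fc5) <- 1
  agg5 <- networkAggregate(fc5, nets)
  expect_equal(unname(as.vector(agg5)), rep(atanh(0.5), 4L), tolerance = 1e-12)

  # direct-loop oracle on a random correlation matrix
  withr::with_seed(4, S <- stats::cov2cor(crossprod(matrix(rnorm(49), 7L)) + diag(7L)))
  nets7 <- c("A", "A", "A", "B", "B", "C", "C")
  agg <- networkAggregate(S, nets7)
  z <- atanh(pmin(pmax(S, -(1 - 1e-7)), 1 - 1e-7))
  for (a in c("A", "B", "C")) for (b in c("A", "B", "C")) {
    ia <- which(nets7 == a); ib <- which(nets7 == b)
    vals <- if (a == b) {
      blk <- z[ia, ia]; blk[upper.tri(blk)]
    } else as.vector(z[ia, ib])
    expect_equal(agg[a, b], mean(vals), tolerance = 1e-12)
  }

  # single-ROI network: within-network value undefined
  aggS <- networkAggregate(S, c("A", "A", "A", "B", "B", "B", "solo"))
  expect_true(is.na(aggS["solo", "solo"]))
  expect_false(is.na(aggS["solo", "A"]))

  expect_error(networkAggregate(S, nets), "labeled")
})

test_that("FC similarity correlates upper triangles", {
  withr::with_seed(5, {
    S1 <- stats::cov2cor(crossprod(matrix(rnorm(25), 5L)) + diag(5L))
    S2 <- stats::cov2cor(crossprod(matrix(rnorm(25), 5L)) + diag(5L))
  })
  sim <- fcSimilarity(list(S1, S2, S1))
  expect_equal(diag(sim), rep(1, 3L))
  expect_equal(sim[1L, 3L], 1, tolerance = 1e-12) # shared covariance
  oracle <- stats::cor(S1[upper.tri(S1)], S2[upper.tri(S2)])
  expect_equal(sim[1L, 2L], oracle, tolerance = 1e-12)
  expect_warning(s <- fcSimilarity(list(S1, matrix(1, 5L, 5L))), "constant")
  expect_true(is.na(s[1L, 2L]))
})

test_that("states from one covariance family are more similar within family", {
  withr::with_seed(6, {
    base1 <- crossprod(matrix(rnorm(64), 8L)) + diag(8L)
    base2 <- crossprod(matrix(rnorm(64), 8L)) + diag(8L)
    fcs <- lapply(list(base1, base1, base2, base2), function(B) {
      stats::cov2cor(B + 0.05 * crossprod(matrix(rnorm(64), 8L)))
    })
  })
  sim <- fcSimilarity(fcs)
  within <- c(sim[1, 2], sim[3, 4])
  between <- c(sim[1, 3], sim[1, 4], sim[2, 3], sim[2, 4])
  expect_gt(min(within), max(between))
})
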