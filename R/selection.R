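# Model-order selection: scan K, record free energy, fractional-occupancy
# statistics, mean lifetime and (optionally) Wilks' lambda; choose K at the
# first local minimum of the free-energy curve. Free energy carries the
# decision; the other statistics are reported diagnostics.

#' First local minimum of a selection curve
#'
#' The smallest K whose value is strictly below its left neighbour and no
#' greater than its right neighbour (so the left edge of a plateau counts,
#' ties break toward smaller K). If no interior local minimum exists, the
#' global argmin (first occurrence) is returned.
#'
#' @param values numeric vector of the statistic per candidate K.
#' @param kValues the candidate K values (default `seq_along(values)`).
#' @return The selected K.
#' @export
firstLocalMinimum <- function(values, kValues = seq_along(values)) {
  ok <- is.finite(values)
  values <- values[ok]; kValues <- kValues[ok]
  if (length(values) < 3L) stop("need at least three values")
  for (i in 2:(length(values) - 1L)) {
    if (values[i] < values[i - 1L] && values[i] <= values[i + 1L]) {
      return(kValues[i])
    }
  }
  kValues[which.min(values)]
}

#' Fractional-occupancy summary of a state time course
#'
#' Per-state fractional occupancy is the column mean of gamma (the
#' proportion of time each state is active); the summary returns its
#' maximum and median across states.
#'
#' @param gamma frames x K matrix with rows summing to 1.
#' @return Named numeric vector `c(maxFo = , medianFo = )`.
#' @export
fractionalOccupancyStats <- function(gamma) {
  if (!length(gamma) || !nrow(gamma)) stop("empty gamma")
  fo <- colMeans(gamma)
  c(maxFo = max(fo), medianFo = stats::median(fo))
}

#' Wilks' lambda of state time courses against stage labels
#'
#' One-way MANOVA statistic Lambda = det(W) / det(W + B) with W and B the
#' within- and between-group scatter matrices of the gamma columns, grouped
#' by stage label. The last gamma column is dropped before computing the
#' scatters (rows of gamma sum to 1, so the full matrix is rank-deficient).
#' Lower values indicate stronger separation of the state time courses by
#' sleep stage.
#'
#' @param gamma frames x K state-probability matrix.
#' @param stageLabels per-frame group labels (>= 2 groups).
#' @return Lambda in (0, 1].
#' @export
wilksLambda <- function(gamma, stageLabels) {
  gamma <- as.matrix(gamma)
  if (nrow(gamma) != length(stageLabels)) {
    stop("gamma and stage labels must have equal length")
  }
  g <- factor(stageLabels)
  if (nlevels(g) < 2L) stop("need at least two stage groups")
  X <- gamma[, -ncol(gamma), drop = FALSE]
  if (!ncol(X)) return(1)
  Tm <- crossprod(scale(X, center = TRUE, scale = FALSE))
  W <- matrix(0, ncol(X), ncol(X))
  for (lev in levels(g)) {
    Xi <- X[g == lev, , drop = FALSE]
    if (nrow(Xi) > 1L) W <- W + crossprod(scale(Xi, center = TRUE, scale = FALSE))
  }
  detT <- determinant(Tm, logarithm = TRUE)
  if (!is.finite(detT$modulus) || detT$sign <= 0) {
    warning("singular total scatter; ridge 1e-10 added", call. = FALSE)
    ridge <- diag(1e-10, ncol(X))
    W <- W + ridge; Tm <- Tm + ridge
  }
  lam <- exp(.logdet(W) - .logdet(Tm))
  min(max(lam, .Machine$double.xmin), 1)
}

#' Scan model orders
#'
#' Fits the HMM (with restarts) at each K in `kRange` and records the
#' converged free energy, maximum and median fractional occupancy, mean
#' state lifetime in seconds, and Wilks' lambda when per-frame stage labels
#' are supplied. `chosenK` is the first local minimum of the free-energy
#' curve. A failed fit is recorded as missing with a warning, not fatally.
#'
#' @param scores frames x D matrix.
#' @param kRange ascending integer vector of candidate state counts.
#' @param segmentIndex optional per-frame segment ids.
#' @param trSeconds seconds per frame (for lifetimes).
#' @param stageLabels optional per-frame stage labels for Wilks' lambda.
#' @param seed master seed (shared across K so fits differ only in K).
#' @param nRestarts,maxIter,tol passed to [fitHmm()].
#' @return An [OrderScan-class].
#' @export
scanOrders <- function(scores, kRange, segmentIndex = NULL, trSeconds = 3,
                       stageLabels = NULL, seed = 1L, nRestarts = 5L,
                       maxIter = 500L, tol = 1e-5) {
  kRange <- as.integer(kRange)
  if (!length(kRange) || is.unsorted(kRange, strictly = TRUE)) {
    stop("kRange must be non-empty and ascending")
  }
  n <- length(kRange)
  fe <- maxFo <- medFo <- mlt <- wl <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      fitHmm(scores, kRange[i], segmentIndex = segmentIndex, seed = seed,
             nRestarts = nRestarts, maxIter = maxIter, tol = tol),
      error = function(e) {
        warning("K = ", kRange[i], " failed: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
    if (is.null(fit)) next
    fe[i] <- fit@freeEnergyTrace[length(fit@freeEnergyTrace)]
    fos <- fractionalOccupancyStats(fit@posteriors@gamma)
    maxFo[i] <- fos["maxFo"]; medFo[i] <- fos["medianFo"]
    lt <- stateLifetimes(fit@posteriors@viterbi, fit@posteriors@segmentIndex,
                         trSeconds, K = kRange[i])
    mlt[i] <- mean(lt, na.rm = TRUE)
    if (!is.null(stageLabels)) {
      wl[i] <- wilksLambda(fit@posteriors@gamma, stageLabels)
    }
  }
  chosen <- firstLocalMinimum(fe, kRange)
  methods::new("OrderScan", kValues = kRange, freeEnergies = fe,
               maxFo = maxFo, medianFo = medFo, meanLifetime = mlt,
               wilksLambda = wl, chosenK = as.integer(chosen))
}
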