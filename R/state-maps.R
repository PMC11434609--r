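# Back-projection of state parameters to ROI space and the derived maps:
# relative activation, per-state FC, network-aggregated Fisher-z FC, and
# between-state FC similarity.

#' Project state parameters back to ROI space
#'
#' ROI-space state mean = mixing %*% state mean (+ channel means); ROI-space
#' covariance = mixing %*% state covariance %*% t(mixing). Back-projected
#' covariances have rank at most D (the number of retained components).
#'
#' @param model a fitted [HmmModel-class] with D = `pca@nComponents`.
#' @param pca the [PcaModel-class] used for the reduction.
#' @return List with `means` (K x R matrix) and `covs` (list of R x R).
#' @export
projectToRoi <- function(model, pca) {
  if (model@D != pca@nComponents) {
    stop("model dimension (", model@D, ") does not match PCA components (",
         pca@nComponents, ")")
  }
  M <- pca@mixing
  means <- sweep(model@means %*% t(M), 2L, pca@channelMeans, "+")
  covs <- lapply(model@covs, function(S) .symmetrize(M %*% S %*% t(M)))
  list(means = means, covs = covs)
}

#' Relative activation maps
#'
#' Subtracts the unweighted across-state mean from each state's ROI mean,
#' giving activation relative to the baseline averaged over all states.
#' Idempotent on already-centered input; columns sum to zero across states.
#'
#' @param stateRoiMeans K x R matrix of per-state ROI means.
#' @return K x R matrix of relative activations.
#' @export
relativeActivation <- function(stateRoiMeans) {
  stateRoiMeans <- as.matrix(stateRoiMeans)
  if (nrow(stateRoiMeans) < 2L) stop("need at least two states")
  sweep(stateRoiMeans, 2L, colMeans(stateRoiMeans))
}

#' State functional-connectivity matrix
#'
#' Normalizes a (projected) state covariance to a correlation matrix.
#' Zero-variance ROIs yield NA rows/columns (flagged with a warning); the
#' diagonal is set to 1 for ROIs with positive variance.
#'
#' @param roiCov symmetric positive-semidefinite R x R covariance.
#' @return R x R correlation matrix.
#' @export
stateFc <- function(roiCov) {
  roiCov <- as.matrix(roiCov)
  d <- diag(roiCov)
  if (any(d < -1e-12)) stop("negative variance on the covariance diagonal")
  zero <- d <= 0
  if (any(zero)) {
    warning(sum(zero), " zero-variance ROI(s); correlations set to NA",
            call. = FALSE)
  }
  s <- sqrt(pmax(d, 0))
  fc <- roiCov / outer(s, s)
  fc[zero, ] <- NA_real_
  fc[, zero] <- NA_real_
  diag(fc)[!zero] <- 1
  .symmetrizeNa(fc)
}

.symmetrizeNa <- function(M) {
  up <- M
  up[lower.tri(up)] <- t(M)[lower.tri(M)]
  up
}

#' Network-aggregated functional connectivity
#'
#' Fisher-transforms every off-diagonal ROI-pair correlation
#' (`atanh(r)`, with r clipped to +/-(1 - 1e-7)) and averages over network
#' blocks: within-network values use unordered pairs i < j (self-pairs
#' excluded); between-network values average all cross pairs. A network with
#' a single ROI has no within-network pairs and is reported NA.
#'
#' @param fc R x R correlation matrix.
#' @param roiNetworks character vector of network labels, one per ROI.
#' @return N x N symmetric matrix of mean Fisher-z connectivity.
#' @export
networkAggregate <- function(fc, roiNetworks) {
  fc <- as.matrix(fc)
  if (length(roiNetworks) != nrow(fc)) stop("every ROI must be labeled")
  nets <- unique(roiNetworks)
  z <- atanh(pmin(pmax(fc, -(1 - 1e-7)), 1 - 1e-7))
  out <- matrix(NA_real_, length(nets), length(nets),
                dimnames = list(nets, nets))
  for (a in seq_along(nets)) {
    ia <- which(roiNetworks == nets[a])
    for (b in a:length(nets)) {
      ib <- which(roiNetworks == nets[b])
      if (a == b) {
        if (length(ia) < 2L) next # single-ROI network: within value undefined
        block <- z[ia, ia, drop = FALSE]
        vals <- block[upper.tri(block)]
      } else {
        vals <- as.vector(z[ia, ib, drop = FALSE])
      }
      out[a, b] <- out[b, a] <- mean(vals)
    }
  }
  out
}

#' Between-state similarity of FC patterns
#'
#' Pearson correlation between the vectorized upper triangles of each pair
#' of state FC matrices. A state with a constant FC vector yields NA entries
#' (flagged with a warning).
#'
#' @param fcList list of K ROI x ROI correlation matrices.
#' @return K x K symmetric correlation matrix with unit diagonal.
#' @export
fcSimilarity <- function(fcList) {
  K <- length(fcList)
  if (K < 2L) stop("need at least two states")
  vecs <- vapply(fcList, function(M) M[upper.tri(M)],
                 numeric(sum(upper.tri(fcList[[1L]]))))
  sds <- apply(vecs, 2L, stats::sd)
  if (any(sds == 0, na.rm = TRUE)) {
    warning("constant FC vector(s); similarity entries set to NA", call. = FALSE)
  }
  suppressWarnings(out <- stats::cor(vecs))
  out[, sds == 0] <- NA_real_
  out[sds == 0, ] <- NA_real_
  diag(out)[sds > 0] <- 1
  out
}
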