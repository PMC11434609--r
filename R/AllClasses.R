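#' Canonical sleep-stage labels
#'
#' The six polysomnography-derived stage labels used throughout the package,
#' in their fixed display and tie-breaking order: Wake, N1, N2, N3, REM,
#' Undefined ("Undefined" marks epochs that could not be scored).
#'
#' @return Character vector of length 6.
#' @export
#' @examples
#' sleepStages()
sleepStages <- function() c("Wake", "N1", "N2", "N3", "REM", "Undefined")

.STAGES <- sleepStages()

#' RoiTimeSeries: a multichannel recording with frame-level metadata
#'
#' Holds one participant's ROI-averaged brain time series as a frames x
#' channels matrix, together with the repetition time (TR, seconds per
#' frame), run-segment boundaries and a per-frame censor mask. Segments are
#' 0-based, half-open `[start, end)` intervals in frame coordinates, as in
#' common neuroimaging tooling; the censor mask is TRUE for frames to keep.
#'
#' @slot data numeric matrix, frames x channels; column names are ROI names.
#' @slot trSeconds positive scalar, seconds per frame.
#' @slot participantId single character label.
#' @slot segments integer matrix with columns `start`, `end` (0-based,
#'   half-open), rows ordered and disjoint.
#' @slot censorMask logical vector, one entry per frame, TRUE = keep.
#' @export
setClass("RoiTimeSeries",
  representation(
    data = "matrix",
    trSeconds = "numeric",
    participantId = "character",
    segments = "matrix",
    censorMask = "logical"
  )
)

setValidity("RoiTimeSeries", function(object) {
  msg <- character()
  n <- nrow(object@data)
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (length(object@trSeconds) != 1L || !is.finite(object@trSeconds) ||
      object@trSeconds <= 0) {
    msg <- c(msg, "trSeconds must be a single positive number")
  }
  if (length(object@censorMask) != n) {
    msg <- c(msg, "censorMask length must equal the number of frames")
  }
  seg <- object@segments
  if (ncol(seg) != 2L) {
    msg <- c(msg, "segments must have two columns (start, end)")
  } else if (nrow(seg) > 0L) {
    if (any(seg[, 1L] < 0L) || any(seg[, 2L] > n) || any(seg[, 2L] <= seg[, 1L])) {
      msg <- c(msg, "segments must be non-empty intervals within [0, frames)")
    }
    if (nrow(seg) > 1L && any(seg[-1L, 1L] < seg[-nrow(seg), 2L])) {
      msg <- c(msg, "segments must be ordered and disjoint")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a RoiTimeSeries
#'
#' @param data frames x channels numeric matrix.
#' @param trSeconds repetition time in seconds.
#' @param participantId participant label.
#' @param segments optional integer matrix of (start, end) 0-based half-open
#'   run intervals; default is one segment spanning all frames.
#' @param censorMask optional logical per-frame keep mask; default all TRUE.
#' @return A [RoiTimeSeries-class] object.
#' @export
RoiTimeSeries <- function(data, trSeconds, participantId = "p1",
                          segments = NULL, censorMask = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (is.null(colnames(data))) {
    colnames(data) <- sprintf("roi%03d", seq_len(ncol(data)))
  }
  if (is.null(segments)) {
    segments <- matrix(c(0L, nrow(data)), nrow = 1L)
  }
  segments <- matrix(as.integer(segments), ncol = 2L,
                     dimnames = list(NULL, c("start", "end")))
  if (is.null(censorMask)) censorMask <- rep(TRUE, nrow(data))
  methods::new("RoiTimeSeries", data = data, trSeconds = as.numeric(trSeconds),
               participantId = as.character(participantId),
               segments = segments, censorMask = as.logical(censorMask))
}

#' ConcatData: censored-and-concatenated group time series
#'
#' Frames from several participants' recordings stacked in participant
#' order with censored frames removed. Per-frame indices record which
#' (post-censoring) segment and which participant each frame came from;
#' a censored frame splits its segment in two, so no state transition is
#' ever counted across a gap.
#'
#' @slot data numeric matrix, total retained frames x channels.
#' @slot segmentIndex integer per-frame contiguous segment id (1-based).
#' @slot participantIndex integer per-frame participant id (1-based).
#' @slot participantIds character vector of participant labels.
#' @slot trSeconds seconds per frame.
#' @export
setClass("ConcatData",
  representation(
    data = "matrix",
    segmentIndex = "integer",
    participantIndex = "integer",
    participantIds = "character",
    trSeconds = "numeric"
  )
)

setValidity("ConcatData", function(object) {
  msg <- character()
  n <- nrow(object@data)
  if (length(object@segmentIndex) != n || length(object@participantIndex) != n) {
    msg <- c(msg, "segmentIndex and participantIndex must match frame count")
  }
  if (n > 0L) {
    d <- diff(object@segmentIndex)
    if (object@segmentIndex[1L] != 1L || any(d < 0L) || any(d > 1L)) {
      msg <- c(msg, "segmentIndex must be contiguous non-decreasing ids starting at 1")
    }
  }
  if (length(msg)) msg else TRUE
})

#' PcaModel: a frozen principal-component reduction
#'
#' Stores the mixing matrix (orthonormal loadings), per-component explained
#' variances and the channel means removed before the SVD, so the same
#' reduction can be re-applied to a held-out recording night and so state
#' parameters can be projected back to ROI space.
#'
#' @slot mixing channels x nComponents orthonormal loading matrix.
#' @slot componentVariances per-component variance explained.
#' @slot totalVariance total variance of the (centered) input.
#' @slot nComponents number of retained components.
#' @slot channelMeans per-channel mean removed before the SVD.
#' @export
setClass("PcaModel",
  representation(
    mixing = "matrix",
    componentVariances = "numeric",
    totalVariance = "numeric",
    nComponents = "integer",
    channelMeans = "numeric"
  )
)

setValidity("PcaModel", function(object) {
  msg <- character()
  if (ncol(object@mixing) != object@nComponents) {
    msg <- c(msg, "mixing must have nComponents columns")
  }
  if (length(object@channelMeans) != nrow(object@mixing)) {
    msg <- c(msg, "channelMeans must have one entry per channel")
  }
  ev <- object@componentVariances / object@totalVariance
  if (any(ev <= 0) || any(ev > 1 + 1e-8)) {
    msg <- c(msg, "explained-variance fractions must lie in (0, 1]")
  }
  if (any(diff(object@componentVariances) > 1e-8)) {
    msg <- c(msg, "componentVariances must be non-increasing")
  }
  if (length(msg)) msg else TRUE
})

#' HypnogramSpec: parameters of a simulated whole-night hypnogram
#'
#' A sleep night is simulated as `nCycles` repetitions of a cycle template,
#' an ordered list of (stage, mean dwell in frames) bouts. Bout durations
#' are drawn from a discretized gamma distribution with the given mean and
#' coefficient of variation (`dwellDispersion`); dispersion 0 gives
#' deterministic dwells. Dwells are floored at one frame.
#'
#' @slot cycleTemplate data.frame with columns `stage` (one of
#'   [sleepStages()]) and `meanDwell` (frames, >= 1).
#' @slot nCycles positive integer.
#' @slot trSeconds seconds per frame.
#' @slot dwellDispersion coefficient of variation (sd/mean) of bout dwells.
#' @export
setClass("HypnogramSpec",
  representation(
    cycleTemplate = "data.frame",
    nCycles = "integer",
    trSeconds = "numeric",
    dwellDispersion = "numeric"
  )
)

setValidity("HypnogramSpec", function(object) {
  msg <- character()
  ct <- object@cycleTemplate
  if (!all(c("stage", "meanDwell") %in% names(ct))) {
    msg <- c(msg, "cycleTemplate needs columns 'stage' and 'meanDwell'")
  } else {
    if (!all(ct$stage %in% .STAGES)) {
      msg <- c(msg, "cycleTemplate stages must come from sleepStages()")
    }
    if (any(ct$meanDwell < 1)) msg <- c(msg, "all mean dwells must be >= 1 frame")
  }
  if (object@nCycles < 1L) msg <- c(msg, "nCycles must be positive")
  if (object@trSeconds <= 0) msg <- c(msg, "trSeconds must be positive")
  if (object@dwellDispersion < 0) msg <- c(msg, "dwellDispersion must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname HypnogramSpec-class
#' @param cycleTemplate,nCycles,trSeconds,dwellDispersion see slots.
#' @return A [HypnogramSpec-class] object.
#' @export
hypnogramSpec <- function(cycleTemplate, nCycles = 1L, trSeconds = 3,
                          dwellDispersion = 0.3) {
  methods::new("HypnogramSpec",
               cycleTemplate = as.data.frame(cycleTemplate),
               nCycles = as.integer(nCycles), trSeconds = as.numeric(trSeconds),
               dwellDispersion = as.numeric(dwellDispersion))
}

#' GenerativeModel: ground truth for synthetic recordings
#'
#' The planted analog of a fitted model: K Gaussian states (mean activation
#' vector and channel covariance per state), a row-stochastic transition
#' matrix, an initial distribution, and stage pools mapping each sleep stage
#' to the subset of states allowed while that stage is ongoing.
#'
#' @slot K number of states.
#' @slot R number of channels.
#' @slot stagePools named list, stage label -> integer vector of state ids.
#' @slot A K x K row-stochastic transition matrix.
#' @slot pi initial state distribution.
#' @slot means K x R matrix of state mean activations.
#' @slot covs list of K positive-definite R x R covariance matrices.
#' @export
setClass("GenerativeModel",
  representation(
    K = "integer", R = "integer", stagePools = "list",
    A = "matrix", pi = "numeric", means = "matrix", covs = "list"
  )
)

setValidity("GenerativeModel", function(object) {
  msg <- character()
  K <- object@K; R <- object@R
  if (!all(dim(object@A) == c(K, K))) msg <- c(msg, "A must be K x K")
  else if (any(abs(rowSums(object@A) - 1) > 1e-12)) {
    msg <- c(msg, "rows of A must sum to 1 (tolerance 1e-12)")
  }
  if (abs(sum(object@pi) - 1) > 1e-12) msg <- c(msg, "pi must sum to 1")
  if (!all(dim(object@means) == c(K, R))) msg <- c(msg, "means must be K x R")
  if (length(object@covs) != K) msg <- c(msg, "one covariance per state required")
  for (k in seq_along(object@covs)) {
    S <- object@covs[[k]]
    if (!isTRUE(all.equal(S, t(S), tolerance = 1e-10))) {
      msg <- c(msg, sprintf("cov %d is not symmetric", k))
    } else if (inherits(try(chol(S), silent = TRUE), "try-error")) {
      msg <- c(msg, sprintf("cov %d is not positive-definite", k))
    }
  }
  pooled <- sort(unique(unlist(object@stagePools)))
  if (!all(seq_len(K) %in% pooled)) {
    msg <- c(msg, "every state must belong to at least one stage pool")
  }
  if (length(object@stagePools) &&
      !all(names(object@stagePools) %in% .STAGES)) {
    msg <- c(msg, "stagePools names must come from sleepStages()")
  }
  if (length(msg)) msg else TRUE
})

#' SyntheticDataset: observations plus the truth that generated them
#'
#' @slot sessions list of [RoiTimeSeries-class], one per participant.
#' @slot truePath list of integer vectors, the planted state path per session.
#' @slot hypnogram list of character vectors, per-frame stage labels.
#' @slot model the [GenerativeModel-class] used.
#' @slot seed master seed used for generation.
#' @export
setClass("SyntheticDataset",
  representation(
    sessions = "list", truePath = "list", hypnogram = "list",
    model = "GenerativeModel", seed = "integer"
  )
)

setValidity("SyntheticDataset", function(object) {
  msg <- character()
  nS <- length(object@sessions)
  if (length(object@truePath) != nS || length(object@hypnogram) != nS) {
    msg <- c(msg, "sessions, truePath and hypnogram must have equal length")
  } else {
    for (i in seq_len(nS)) {
      n <- nrow(object@sessions[[i]]@data)
      if (length(object@truePath[[i]]) != n ||
          length(object@hypnogram[[i]]) != n) {
        msg <- c(msg, sprintf("session %d: frame counts disagree", i))
        next
      }
      pools <- object@model@stagePools
      ok <- vapply(seq_len(n), function(t) {
        object@truePath[[i]][t] %in% pools[[object@hypnogram[[i]][t]]]
      }, logical(1))
      if (!all(ok)) {
        msg <- c(msg, sprintf("session %d: state outside its stage pool", i))
      }
    }
  }
  if (length(msg)) msg else TRUE
})

#' HmmModel: variational-Bayes Gaussian hidden Markov model
#'
#' Conjugate-exponential Gaussian HMM. The initial distribution and each
#' transition-matrix row carry Dirichlet priors/posteriors; each state's
#' Gaussian carries a Normal-Wishart prior/posterior (hyperparameters
#' `m`, `beta`, `W`, `nu` with the Wishart on the precision matrix).
#' Point estimates are posterior expectations: `pi` and `A` from Dirichlet
#' means, state means from `m`, state covariances from `(nu W)^{-1}`.
#'
#' @slot K number of states.
#' @slot D observation dimension (number of retained components).
#' @slot priors list: `alphaPi` (K), `alphaA` (K x K), `m0` (D), `beta0`,
#'   `W0` (D x D), `nu0`.
#' @slot posteriors list with the same fields updated by the data:
#'   `alphaPi`, `alphaA`, `m` (K x D), `beta` (K), `W` (list of D x D), `nu` (K).
#' @slot pi point estimate of the initial distribution.
#' @slot A point estimate of the transition matrix (rows sum to 1).
#' @slot means K x D point-estimate state means.
#' @slot covs list of K D x D point-estimate state covariances.
#' @export
setClass("HmmModel",
  representation(
    K = "integer", D = "integer",
    priors = "list", posteriors = "list",
    pi = "numeric", A = "matrix", means = "matrix", covs = "list"
  )
)

setValidity("HmmModel", function(object) {
  msg <- character()
  K <- object@K; D <- object@D
  if (any(abs(rowSums(object@A) - 1) > 1e-10)) {
    msg <- c(msg, "rows of A must sum to 1 (tolerance 1e-10)")
  }
  if (!all(dim(object@means) == c(K, D))) msg <- c(msg, "means must be K x D")
  if (object@priors$nu0 < D) msg <- c(msg, "nu0 must be >= D")
  if (any(object@priors$alphaPi <= 0) || any(object@priors$alphaA <= 0)) {
    msg <- c(msg, "Dirichlet concentrations must be positive")
  }
  if (length(msg)) msg else TRUE
})

#' StatePosteriors: inferred state time courses
#'
#' @slot gamma frames x K per-frame state probabilities (rows sum to 1).
#' @slot xi K x K pairwise transition expectations summed over all
#'   within-segment frame pairs.
#' @slot loglik per-segment log-evidence contributions (under the
#'   variational expected parameters).
#' @slot viterbi integer per-frame most-probable path (1-based state ids).
#' @slot segmentIndex integer per-frame segment id the posteriors refer to.
#' @export
setClass("StatePosteriors",
  representation(
    gamma = "matrix", xi = "matrix", loglik = "numeric",
    viterbi = "integer", segmentIndex = "integer"
  )
)

setValidity("StatePosteriors", function(object) {
  msg <- character()
  n <- nrow(object@gamma)
  if (n > 0L && any(abs(rowSums(object@gamma) - 1) > 1e-8)) {
    msg <- c(msg, "gamma rows must sum to 1 (tolerance 1e-8)")
  }
  if (any(object@xi < -1e-12)) msg <- c(msg, "xi entries must be >= 0")
  K <- ncol(object@gamma)
  if (length(object@viterbi) &&
      (min(object@viterbi) < 1L || max(object@viterbi) > K)) {
    msg <- c(msg, "viterbi entries must be valid state ids")
  }
  if (length(msg)) msg else TRUE
})

#' FitResult: a fitted model with its optimization trace
#'
#' @slot model the fitted [HmmModel-class].
#' @slot posteriors final [StatePosteriors-class].
#' @slot freeEnergyTrace per-iteration variational free energy (non-increasing).
#' @slot converged logical.
#' @slot seed seed of the winning restart.
#' @slot nRestartsUsed number of restarts run.
#' @export
setClass("FitResult",
  representation(
    model = "HmmModel", posteriors = "StatePosteriors",
    freeEnergyTrace = "numeric", converged = "logical",
    seed = "integer", nRestartsUsed = "integer"
  )
)

setValidity("FitResult", function(object) {
  tr <- object@freeEnergyTrace
  if (length(tr) > 1L && any(diff(tr) > 1e-8 * pmax(1, abs(tr[-length(tr)])))) {
    return("freeEnergyTrace must be non-increasing (1e-8 relative slack)")
  }
  TRUE
})

#' OrderScan: model-order selection statistics
#'
#' One row per candidate number of states K: converged free energy, maximum
#' and median fractional occupancy, mean state lifetime in seconds, and
#' (when stage labels are available) Wilks' lambda of the state time courses
#' against the stage labels. `chosenK` is the first local minimum of the
#' free-energy curve (global argmin fallback).
#'
#' @slot kValues,freeEnergies,maxFo,medianFo,meanLifetime,wilksLambda aligned
#'   numeric vectors.
#' @slot chosenK selected model order.
#' @export
setClass("OrderScan",
  representation(
    kValues = "integer", freeEnergies = "numeric", maxFo = "numeric",
    medianFo = "numeric", meanLifetime = "numeric", wilksLambda = "numeric",
    chosenK = "integer"
  )
)

setValidity("OrderScan", function(object) {
  n <- length(object@kValues)
  lens <- c(length(object@freeEnergies), length(object@maxFo),
            length(object@medianFo), length(object@meanLifetime),
            length(object@wilksLambda))
  if (any(lens != n)) return("all statistic vectors must align with kValues")
  fo <- c(object@maxFo, object@medianFo)
  if (any(fo < -1e-12 | fo > 1 + 1e-12, na.rm = TRUE)) {
    return("fractional occupancies must lie in [0, 1]")
  }
  wl <- object@wilksLambda
  if (any(wl <= 0 | wl > 1 + 1e-12, na.rm = TRUE)) {
    return("Wilks' lambda must lie in (0, 1]")
  }
  TRUE
})

#' ModulePartition: transition-matrix community structure
#'
#' @slot assignment per-state module index (1-based, contiguous).
#' @slot q directed (Leicht-Newman) modularity score of the partition.
#' @slot nModules number of modules.
#' @export
setClass("ModulePartition",
  representation(assignment = "integer", q = "numeric", nModules = "integer")
)

setValidity("ModulePartition", function(object) {
  msg <- character()
  a <- object@assignment
  if (!identical(sort(unique(a)), seq_len(object@nModules))) {
    msg <- c(msg, "module indices must be contiguous from 1")
  }
  if (object@nModules > length(a)) msg <- c(msg, "more modules than states")
  if (object@q < -1 - 1e-12 || object@q > 1 + 1e-12) {
    msg <- c(msg, "q must lie in [-1, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' StateSummary: temporal statistics and stage correspondence per state
#'
#' @slot fo per-state fractional occupancy (sums to 1).
#' @slot meanLifetimeS per-state mean dwell in seconds (NA if never visited).
#' @slot stageDist K x 6 row-normalized time-in-stage matrix, columns in
#'   [sleepStages()] order.
#' @slot wtaStage winner-takes-all stage label per state.
#' @slot trSeconds seconds per frame used for lifetimes.
#' @export
setClass("StateSummary",
  representation(
    fo = "numeric", meanLifetimeS = "numeric", stageDist = "matrix",
    wtaStage = "character", trSeconds = "numeric"
  )
)

setValidity("StateSummary", function(object) {
  msg <- character()
  if (abs(sum(object@fo) - 1) > 1e-8) msg <- c(msg, "fo must sum to 1")
  rs <- rowSums(object@stageDist)
  if (any(abs(rs[rs > 0] - 1) > 1e-8)) {
    msg <- c(msg, "stageDist rows must sum to 1")
  }
  lt <- object@meanLifetimeS
  if (any(lt < object@trSeconds - 1e-9, na.rm = TRUE)) {
    msg <- c(msg, "mean lifetimes cannot be shorter than one frame")
  }
  if (length(msg)) msg else TRUE
})
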