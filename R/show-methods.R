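# show() methods and light accessors.

setMethod("show", "RoiTimeSeries", function(object) {
  cat(sprintf("RoiTimeSeries '%s': %d frames x %d channels, TR %.3g s, %d segment(s), %d censored frame(s)\n",
              object@participantId, nrow(object@data), ncol(object@data),
              object@trSeconds, nrow(object@segments),
              sum(!object@censorMask)))
})

setMethod("show", "ConcatData", function(object) {
  cat(sprintf("ConcatData: %d frames x %d channels, %d segments, %d participants\n",
              nrow(object@data), ncol(object@data),
              max(object@segmentIndex, 0L), length(object@participantIds)))
})

setMethod("show", "PcaModel", function(object) {
  cat(sprintf("PcaModel: %d of %d channels' components, %.1f%% variance retained\n",
              object@nComponents, nrow(object@mixing),
              100 * sum(object@componentVariances) / object@totalVariance))
})

setMethod("show", "GenerativeModel", function(object) {
  cat(sprintf("GenerativeModel: K = %d states, %d channels, %d stage pools\n",
              object@K, object@R, length(object@stagePools)))
})

setMethod("show", "SyntheticDataset", function(object) {
  frames <- sum(vapply(object@sessions, function(s) nrow(s@data), 0L))
  cat(sprintf("SyntheticDataset: %d participant(s), %d total frames, K_true = %d, seed %d\n",
              length(object@sessions), frames, object@model@K, object@seed))
})

setMethod("show", "HmmModel", function(object) {
  cat(sprintf("HmmModel: K = %d Gaussian states in D = %d dimensions\n",
              object@K, object@D))
  cat("  transition diagonal:",
      paste(sprintf("%.2f", diag(object@A)), collapse = " "), "\n")
})

setMethod("show", "StatePosteriors", function(object) {
  cat(sprintf("StatePosteriors: %d frames x %d states, %d segment(s), log-evidence %.2f\n",
              nrow(object@gamma), ncol(object@gamma),
              length(object@loglik), sum(object@loglik)))
})

setMethod("show", "FitResult", function(object) {
  fe <- object@freeEnergyTrace
  cat(sprintf("FitResult: K = %d, free energy %.2f after %d iterations (%s), seed %d\n",
              object@model@K, fe[length(fe)], length(fe),
              if (object@converged) "converged" else "NOT converged",
              object@seed))
})

setMethod("show", "OrderScan", function(object) {
  cat("OrderScan over K =", paste(range(object@kValues), collapse = ".."),
      "-> chosen K =", object@chosenK, "\n")
  print(as.data.frame(object))
})

setMethod("show", "ModulePartition", function(object) {
  cat(sprintf("ModulePartition: %d modules over %d states, Q = %.4f\n",
              object@nModules, length(object@assignment), object@q))
})

setMethod("show", "StateSummary", function(object) {
  cat(sprintf("StateSummary: %d states; FO sums to %.6f; lifetimes %.1f-%.1f s\n",
              length(object@fo), sum(object@fo),
              min(object@meanLifetimeS, na.rm = TRUE),
              max(object@meanLifetimeS, na.rm = TRUE)))
})

#' @describeIn OrderScan-class tabulate the scan
#' @param x an OrderScan.
#' @param ... ignored.
#' @export
setMethod("as.data.frame", "OrderScan", function(x, ...) {
  data.frame(k = x@kValues, freeEnergy = x@freeEnergies, maxFo = x@maxFo,
             medianFo = x@medianFo, meanLifetimeS = x@meanLifetime,
             wilksLambda = x@wilksLambda)
})

#' Accessors
#'
#' Small accessor family for the core classes: number of states, transition
#' matrix, state means/covariances, initial distribution, state
#' probabilities and Viterbi path, module assignment and modularity score.
#'
#' @param object a package object.
#' @return The requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("nStates", function(object) standardGeneric("nStates"))
#' @rdname accessors
#' @export
setMethod("nStates", "HmmModel", function(object) object@K)
#' @rdname accessors
#' @export
setMethod("nStates", "FitResult", function(object) object@model@K)

#' @rdname accessors
#' @export
setGeneric("transitionMatrix", function(object) standardGeneric("transitionMatrix"))
#' @rdname accessors
#' @export
setMethod("transitionMatrix", "HmmModel", function(object) object@A)
#' @rdname accessors
#' @export
setMethod("transitionMatrix", "FitResult", function(object) object@model@A)
#' @rdname accessors
#' @export
setMethod("transitionMatrix", "GenerativeModel", function(object) object@A)

#' @rdname accessors
#' @export
setGeneric("stateMeans", function(object) standardGeneric("stateMeans"))
#' @rdname accessors
#' @export
setMethod("stateMeans", "HmmModel", function(object) object@means)
#' @rdname accessors
#' @export
setMethod("stateMeans", "FitResult", function(object) object@model@means)
#' @rdname accessors
#' @export
setMethod("stateMeans", "GenerativeModel", function(object) object@means)

#' @rdname accessors
#' @export
setGeneric("stateCovs", function(object) standardGeneric("stateCovs"))
#' @rdname accessors
#' @export
setMethod("stateCovs", "HmmModel", function(object) object@covs)
#' @rdname accessors
#' @export
setMethod("stateCovs", "FitResult", function(object) object@model@covs)

#' @rdname accessors
#' @export
setGeneric("stateProbabilities", function(object) standardGeneric("stateProbabilities"))
#' @rdname accessors
#' @export
setMethod("stateProbabilities", "StatePosteriors", function(object) object@gamma)
#' @rdname accessors
#' @export
setMethod("stateProbabilities", "FitResult", function(object) object@posteriors@gamma)

#' @rdname accessors
#' @export
setGeneric("viterbiPath", function(object) standardGeneric("viterbiPath"))
#' @rdname accessors
#' @export
setMethod("viterbiPath", "StatePosteriors", function(object) object@viterbi)
#' @rdname accessors
#' @export
setMethod("viterbiPath", "FitResult", function(object) object@posteriors@viterbi)

#' @rdname accessors
#' @export
setGeneric("hmmModel", function(object) standardGeneric("hmmModel"))
#' @rdname accessors
#' @export
setMethod("hmmModel", "FitResult", function(object) object@model)

#' @rdname accessors
#' @export
setGeneric("statePosteriors", function(object) standardGeneric("statePosteriors"))
#' @rdname accessors
#' @export
setMethod("statePosteriors", "FitResult", function(object) object@posteriors)

#' @rdname accessors
#' @export
setGeneric("freeEnergyTrace", function(object) standardGeneric("freeEnergyTrace"))
#' @rdname accessors
#' @export
setMethod("freeEnergyTrace", "FitResult", function(object) object@freeEnergyTrace)

#' @rdname accessors
#' @export
setGeneric("moduleAssignment", function(object) standardGeneric("moduleAssignment"))
#' @rdname accessors
#' @export
setMethod("moduleAssignment", "ModulePartition", function(object) object@assignment)

#' @rdname accessors
#' @export
setGeneric("modularityScore", function(object) standardGeneric("modularityScore"))
#' @rdname accessors
#' @export
setMethod("modularityScore", "ModulePartition", function(object) object@q)

#' @rdname accessors
#' @export
setGeneric("chosenK", function(object) standardGeneric("chosenK"))
#' @rdname accessors
#' @export
setMethod("chosenK", "OrderScan", function(object) object@chosenK)
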