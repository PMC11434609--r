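# File formats: tab-separated observation matrices with a YAML sidecar
# (TR, participant, segments, censor mask), one-label-per-line hypnograms,
# and a two-column ROI -> network table. All coordinates on disk are
# 0-based half-open, matching the in-memory convention.

.fmtNum <- function(x) sprintf("%.17g", x)

#' Write an observation matrix and its sidecar
#'
#' @param ts a [RoiTimeSeries-class].
#' @param path output path for the tab-separated matrix (header row of ROI
#'   names, one row per frame).
#' @param sidecarPath output path for the YAML sidecar; default `path` with
#'   a `.yaml` extension appended.
#' @return Invisibly, `path`.
#' @export
writeRoiMatrix <- function(ts, path, sidecarPath = paste0(path, ".yaml")) {
  stopifnot(methods::is(ts, "RoiTimeSeries"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(colnames(ts@data), collapse = "\t"), con)
  body <- apply(ts@data, 1L, function(r) paste(.fmtNum(r), collapse = "\t"))
  writeLines(body, con)
  sidecar <- list(
    tr_seconds = ts@trSeconds,
    participant_id = ts@participantId,
    segments = lapply(seq_len(nrow(ts@segments)), function(i) {
      list(start = ts@segments[i, 1L], end = ts@segments[i, 2L])
    }),
    censor_mask = as.integer(ts@censorMask)
  )
  yaml::write_yaml(sidecar, sidecarPath)
  invisible(path)
}

#' Read an observation matrix with its sidecar
#'
#' @param path tab-separated frames x ROIs matrix with a header row.
#' @param sidecarPath YAML sidecar (see [writeRoiMatrix()]).
#' @return A [RoiTimeSeries-class].
#' @export
readRoiMatrix <- function(path, sidecarPath = paste0(path, ".yaml")) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(sidecarPath)) stop("no such sidecar: ", sidecarPath)
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  storage.mode(m) <- "double"
  sc <- yaml::read_yaml(sidecarPath)
  need <- c("tr_seconds", "participant_id", "segments", "censor_mask")
  if (!all(need %in% names(sc))) {
    stop("sidecar is missing fields: ",
         paste(setdiff(need, names(sc)), collapse = ", "))
  }
  if (length(sc$censor_mask) != nrow(m)) {
    stop("sidecar censor mask length (", length(sc$censor_mask),
         ") does not match matrix frames (", nrow(m), ")")
  }
  seg <- do.call(rbind, lapply(sc$segments, function(s) c(s$start, s$end)))
  RoiTimeSeries(m, trSeconds = sc$tr_seconds,
                participantId = sc$participant_id,
                segments = seg, censorMask = as.logical(sc$censor_mask))
}

#' Read / write a hypnogram
#'
#' One stage label per line, labels restricted to [sleepStages()].
#'
#' @param path file path.
#' @return Character vector of per-frame stage labels.
#' @export
readHypnogram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  labs <- readLines(path)
  labs <- labs[nzchar(labs)]
  bad <- setdiff(unique(labs), .STAGES)
  if (length(bad)) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(.STAGES, collapse = ", "), ")")
  }
  labs
}

#' @rdname readHypnogram
#' @param labels character vector of stage labels.
#' @export
writeHypnogram <- function(labels, path) {
  bad <- setdiff(unique(labels), .STAGES)
  if (length(bad)) stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  writeLines(labels, path)
  invisible(path)
}

#' Read an ROI-to-network lookup table
#'
#' Tab-separated, two columns `roi` and `network`, one row per ROI.
#'
#' @param path file path.
#' @return Named character vector, network label per ROI name.
#' @export
readNetworkTable <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("roi", "network") %in% names(tab))) {
    stop("network table needs columns 'roi' and 'network'")
  }
  stats::setNames(as.character(tab$network), tab$roi)
}

#' Standardize a recording per channel
#'
#' Scales each channel to mean 0 and sample standard deviation 1 (n-1
#' denominator), with moments computed over the participant's uncensored
#' frames only; censored frames receive the same affine transform.
#' Idempotent.
#'
#' @param ts a [RoiTimeSeries-class].
#' @return The standardized [RoiTimeSeries-class].
#' @export
standardize <- function(ts) {
  stopifnot(methods::is(ts, "RoiTimeSeries"))
  keep <- ts@censorMask
  if (sum(keep) < 2L) stop("need at least two uncensored frames")
  mu <- colMeans(ts@data[keep, , drop = FALSE])
  sdv <- apply(ts@data[keep, , drop = FALSE], 2L, stats::sd)
  zero <- which(sdv <= 0 | !is.finite(sdv))
  if (length(zero)) {
    stop("zero-variance channel(s): ",
         paste(colnames(ts@data)[zero], collapse = ", "))
  }
  out <- ts
  out@data <- sweep(sweep(ts@data, 2L, mu), 2L, sdv, "/")
  out
}

#' Concatenate recordings across participants
#'
#' Stacks frames in participant order, drops censored frames, and keeps
#' per-frame segment and participant indices. A censored frame splits its
#' run segment in two, so downstream inference never counts a transition
#' across the gap.
#'
#' @param sessions list of [RoiTimeSeries-class] with identical channels.
#' @return A [ConcatData-class].
#' @export
concatenateSessions <- function(sessions) {
  if (!length(sessions)) stop("empty session list")
  ref <- colnames(sessions[[1L]]@data)
  tr <- sessions[[1L]]@trSeconds
  blocks <- list(); segIdx <- list(); partIdx <- list()
  segCounter <- 0L
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    if (!identical(colnames(s@data), ref)) {
      stop("session ", i, ": channel names/order differ from session 1")
    }
    if (abs(s@trSeconds - tr) > 1e-12) {
      stop("session ", i, ": TR differs from session 1")
    }
    keepSeg <- integer(nrow(s@data)) # 0 = dropped
    for (r in seq_len(nrow(s@segments))) {
      fr <- (s@segments[r, 1L] + 1L):s@segments[r, 2L]
      kept <- fr[s@censorMask[fr]]
      if (!length(kept)) next
      # censoring splits a run: new segment at each gap
      brk <- c(TRUE, diff(kept) > 1L)
      keepSeg[kept] <- segCounter + cumsum(brk)
      segCounter <- segCounter + sum(brk)
    }
    sel <- which(keepSeg > 0L)
    blocks[[i]] <- s@data[sel, , drop = FALSE]
    segIdx[[i]] <- keepSeg[sel]
    partIdx[[i]] <- rep(i, length(sel))
  }
  methods::new("ConcatData",
               data = do.call(rbind, blocks),
               segmentIndex = as.integer(unlist(segIdx)),
               participantIndex = as.integer(unlist(partIdx)),
               participantIds = vapply(sessions, function(s) s@participantId, ""),
               trSeconds = tr)
}

#' Fit a principal-component reduction
#'
#' Column-centers the concatenated data and computes the top
#' `nComponents` right singular vectors (the mixing matrix). Scores are the
#' centered data times the mixing matrix, not whitened, so fitted state
#' covariances remain interpretable after back-projection.
#'
#' @param concat a [ConcatData-class] (or plain matrix).
#' @param nComponents number of components to retain.
#' @return List with `model` (a [PcaModel-class]) and `scores`
#'   (frames x nComponents matrix).
#' @export
fitPca <- function(concat, nComponents) {
  X <- if (methods::is(concat, "ConcatData")) concat@data else as.matrix(concat)
  nComponents <- as.integer(nComponents)
  if (nComponents < 1L || nComponents > min(dim(X))) {
    stop("nComponents must be in [1, min(frames, channels)]")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  vars <- pc$sdev^2
  model <- methods::new("PcaModel",
    mixing = pc$rotation[, seq_len(nComponents), drop = FALSE],
    componentVariances = vars[seq_len(nComponents)],
    totalVariance = sum(vars),
    nComponents = nComponents,
    channelMeans = if (is.numeric(pc$center)) pc$center else colMeans(X))
  list(model = model, scores = pc$x[, seq_len(nComponents), drop = FALSE])
}

#' Apply a frozen principal-component reduction
#'
#' Projects new data through an existing [PcaModel-class] (training-night
#' channel means and mixing matrix), as required when a trained model is
#' generalized to a held-out night.
#'
#' @param pca a [PcaModel-class].
#' @param concat a [ConcatData-class] or matrix with matching channels.
#' @return frames x nComponents score matrix.
#' @export
projectScores <- function(pca, concat) {
  X <- if (methods::is(concat, "ConcatData")) concat@data else as.matrix(concat)
  if (ncol(X) != nrow(pca@mixing)) {
    stop("channel count does not match the PCA model")
  }
  sweep(X, 2L, pca@channelMeans) %*% pca@mixing
}

#' Fraction of variance explained by the retained components
#'
#' @param pca a [PcaModel-class].
#' @return Scalar in (0, 1].
#' @export
explainedVariance <- function(pca) {
  sum(pca@componentVariances) / pca@totalVariance
}
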