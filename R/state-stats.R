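# Per-state temporal statistics, stage correspondence and cross-night
# similarity.

#' Mean state lifetimes
#'
#' A visit is a maximal run of one state within one segment; visits cut off
#' by a segment boundary count at their observed length (excluding them
#' would bias short recordings). The mean visit length per state, times the
#' TR, gives the lifetime in seconds. States never visited get NA.
#'
#' @param path integer per-frame state indices (e.g. a Viterbi path).
#' @param segmentIndex per-frame segment ids (NULL for a single segment).
#' @param trSeconds seconds per frame.
#' @param K number of states (default `max(path)`).
#' @return Numeric vector of per-state mean lifetimes in seconds.
#' @export
stateLifetimes <- function(path, segmentIndex = NULL, trSeconds = 3,
                           K = max(path)) {
  if (is.null(segmentIndex)) segmentIndex <- rep(1L, length(path))
  if (length(segmentIndex) != length(path)) {
    stop("path and segmentIndex must align")
  }
  rng <- .segmentRanges(as.integer(segmentIndex))
  lens <- vector("list", nrow(rng))
  states <- vector("list", nrow(rng))
  for (s in seq_len(nrow(rng))) {
    r <- rle(path[rng[s, 1L]:rng[s, 2L]])
    lens[[s]] <- r$lengths; states[[s]] <- r$values
  }
  lens <- unlist(lens); states <- unlist(states)
  out <- rep(NA_real_, K)
  agg <- tapply(lens, factor(states, levels = seq_len(K)), mean)
  out[!is.na(agg)] <- agg[!is.na(agg)] * trSeconds
  out
}

#' Per-state sleep-stage distribution
#'
#' Entry (k, s) is the fraction of state k's frames spent in stage s
#' (row-normalized co-occurrence of the state path with the hypnogram).
#' Columns follow [sleepStages()] order. A never-visited state keeps an
#' all-zero row.
#'
#' @param path integer per-frame state indices.
#' @param hypnogram character per-frame stage labels.
#' @param K number of states (default `max(path)`).
#' @return K x 6 row-normalized matrix.
#' @export
stageDistribution <- function(path, hypnogram, K = max(path)) {
  if (length(path) != length(hypnogram)) {
    stop("path and hypnogram must have equal length")
  }
  tab <- table(factor(path, levels = seq_len(K)),
               factor(hypnogram, levels = .STAGES))
  m <- matrix(as.numeric(tab), K, length(.STAGES),
              dimnames = list(sprintf("state%d", seq_len(K)), .STAGES))
  rs <- rowSums(m)
  m[rs > 0, ] <- m[rs > 0, , drop = FALSE] / rs[rs > 0]
  m
}

#' Winner-takes-all stage assignment
#'
#' Assigns each state to the sleep stage it most frequently co-occurs with
#' (row argmax of the stage distribution). Ties break by the fixed stage
#' order Wake > N1 > N2 > N3 > REM > Undefined.
#'
#' @param stageDist K x 6 stage-distribution matrix, columns in
#'   [sleepStages()] order.
#' @return Character vector of per-state stage labels.
#' @export
winnerTakesAll <- function(stageDist) {
  stageDist <- as.matrix(stageDist)
  if (any(rowSums(stageDist) == 0)) {
    stop("all-zero stage-distribution row (state never visited)")
  }
  .STAGES[max.col(stageDist, ties.method = "first")]
}

#' Cross-night similarity of stage distributions
#'
#' Pearson correlation between two flattened K x 6 stage-distribution
#' matrices with states aligned by the frozen model (the training-night
#' state indices are reused when the model is applied to the held-out
#' night). A two-sided p-value from the t transform is reported alongside
#' but is never used for any decision in the pipeline.
#'
#' @param distA,distB K x 6 stage-distribution matrices of the two nights.
#' @return List with `r` and `p`.
#' @export
crossNightCorrelation <- function(distA, distB) {
  if (!identical(dim(distA), dim(distB))) stop("shapes must match")
  a <- as.vector(distA); b <- as.vector(distB)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance in a stage-distribution matrix")
  }
  ct <- stats::cor.test(a, b)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Summarize states: occupancy, lifetime and stage correspondence
#'
#' @param posteriors a [StatePosteriors-class].
#' @param hypnogram per-frame stage labels aligned with the decoded frames.
#' @param trSeconds seconds per frame.
#' @return A [StateSummary-class].
#' @export
stateSummary <- function(posteriors, hypnogram, trSeconds = 3) {
  K <- ncol(posteriors@gamma)
  fo <- colMeans(posteriors@gamma)
  lt <- stateLifetimes(posteriors@viterbi, posteriors@segmentIndex,
                       trSeconds, K = K)
  sd6 <- stageDistribution(posteriors@viterbi, hypnogram, K = K)
  wta <- rep(NA_character_, K)
  visited <- rowSums(sd6) > 0
  if (any(visited)) {
    wta[visited] <- winnerTakesAll(sd6[visited, , drop = FALSE])
  }
  methods::new("StateSummary", fo = fo, meanLifetimeS = lt, stageDist = sd6,
               wtaStage = wta, trSeconds = trSeconds)
}
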