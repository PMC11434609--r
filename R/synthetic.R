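# Synthetic whole-night recordings with known ground truth: a cycling
# hypnogram, a state path nested within the hypnogram's stage bouts, and
# multivariate-Gaussian emissions per state.

#' Default hypnogram specification
#'
#' A compressed Wake-N1-N2-N3-N2-REM(-Undefined) cycle whose bout dwells put
#' decoded state lifetimes in the 8.7-36 s range at TR = 3 s (roughly 3-12
#' frames per bout, mean near 12 s). Repeated `nCycles` times.
#'
#' @param nCycles number of sleep cycles (default 43, about 2000 frames).
#' @param trSeconds seconds per frame.
#' @param dwellDispersion coefficient of variation of bout dwells.
#' @return A [HypnogramSpec-class].
#' @export
defaultHypnogramSpec <- function(nCycles = 43L, trSeconds = 3,
                                 dwellDispersion = 0.3) {
  template <- data.frame(
    stage = c("Wake", "N1", "N2", "N3", "N2", "REM", "Undefined"),
    meanDwell = c(8, 4, 10, 8, 6, 8, 3)
  )
  hypnogramSpec(template, nCycles = nCycles, trSeconds = trSeconds,
                dwellDispersion = dwellDispersion)
}

#' Default generative model
#'
#' Six Gaussian states in `R` channels. With `pools = "stage"` each of the
#' six stages owns one state (disjoint singleton pools), so the planted
#' stage-state nesting is exact: the natural setting for stage-correspondence
#' and cross-night experiments. With `pools = "shared"` every stage pools all
#' states, so the planted path is a single Markov chain governed by `A`:
#' the natural setting for transition-matrix recovery experiments.
#'
#' State means are drawn once from the given `seed` with per-channel scale
#' `separation`; covariances are distinct random perturbations of identity
#' (guaranteed positive-definite). Self-transition probability defaults to
#' 0.75, i.e. a geometric mean dwell of 4 frames = 12 s at TR 3 s.
#'
#' @param K number of states (default 6).
#' @param R number of channels (default 20).
#' @param seed seed fixing the model parameters.
#' @param selfTransition shared diagonal of the transition matrix.
#' @param separation standard deviation of state mean entries.
#' @param pools `"stage"` (disjoint, one state per stage) or `"shared"`.
#' @return A [GenerativeModel-class].
#' @export
defaultGenerativeModel <- function(K = 6L, R = 20L, seed = 1L,
                                   selfTransition = 0.75, separation = 1.5,
                                   pools = c("stage", "shared")) {
  pools <- match.arg(pools)
  K <- as.integer(K); R <- as.integer(R)
  if (pools == "stage" && K != 6L) {
    stop("stage pools require K = 6 (one state per stage)")
  }
  A <- matrix((1 - selfTransition) / (K - 1), K, K)
  diag(A) <- selfTransition
  stagePools <- if (pools == "stage") {
    stats::setNames(as.list(seq_len(6L)), .STAGES)
  } else {
    stats::setNames(rep(list(seq_len(K)), 6L), .STAGES)
  }
  .withSeed(seed, {
    means <- matrix(stats::rnorm(K * R, sd = separation), K, R)
    covs <- lapply(seq_len(K), function(k) {
      G <- matrix(stats::rnorm(R * R), R, R)
      .symmetrize(0.5 * diag(R) + 0.5 * crossprod(G) / R)
    })
  })
  methods::new("GenerativeModel", K = K, R = R, stagePools = stagePools,
               A = A, pi = rep(1 / K, K), means = means, covs = covs)
}

#' Simulate a hypnogram
#'
#' Repeats the cycle template `nCycles` times; each bout's dwell is drawn
#' from a discretized gamma distribution with the template's mean and the
#' spec's coefficient of variation (shape `1/cv^2`, scale `mean * cv^2`),
#' floored at one frame. Dispersion 0 gives deterministic dwells.
#'
#' @param spec a [HypnogramSpec-class].
#' @param seed integer seed.
#' @return Character vector of per-frame stage labels.
#' @export
simulateHypnogram <- function(spec, seed = 1L) {
  methods::validObject(spec)
  ct <- spec@cycleTemplate
  if (any(ct$meanDwell <= 0)) stop("dwell means must be positive")
  cv <- spec@dwellDispersion
  .withSeed(seed, {
    bouts <- do.call(c, lapply(seq_len(spec@nCycles), function(cyc) {
      unlist(lapply(seq_len(nrow(ct)), function(i) {
        m <- ct$meanDwell[i]
        d <- if (cv == 0) round(m) else {
          round(stats::rgamma(1L, shape = 1 / cv^2, scale = m * cv^2))
        }
        rep(ct$stage[i], max(1L, d))
      }))
    }))
  })
  bouts
}

#' Simulate a state path nested within a hypnogram
#'
#' Within each stage bout a Markov chain runs on that stage's pool of
#' states, using the model's transition matrix restricted to the pool and
#' row-renormalized. At every bout boundary the chain re-initializes from
#' the initial distribution restricted to the new pool.
#'
#' @param hypnogram character vector of per-frame stage labels.
#' @param model a [GenerativeModel-class].
#' @param seed integer seed.
#' @return Integer vector of per-frame state indices (1-based).
#' @export
simulateStateSequence <- function(hypnogram, model, seed = 1L) {
  stages <- unique(hypnogram)
  for (s in stages) {
    pool <- model@stagePools[[s]]
    if (is.null(pool) || !length(pool)) {
      stop("stage '", s, "' occurs in the hypnogram but has an empty state pool")
    }
  }
  r <- rle(hypnogram)
  .withSeed(seed, {
    path <- integer(0)
    for (b in seq_along(r$values)) {
      pool <- model@stagePools[[r$values[b]]]
      len <- r$lengths[b]
      p0 <- model@pi[pool]
      p0 <- if (sum(p0) > 0) p0 / sum(p0) else rep(1 / length(pool), length(pool))
      Ar <- model@A[pool, pool, drop = FALSE]
      rs <- rowSums(Ar)
      for (i in which(rs == 0)) Ar[i, ] <- 1 / length(pool)
      Ar <- Ar / rowSums(Ar)
      x <- integer(len)
      x[1L] <- sample.int(length(pool), 1L, prob = p0)
      if (len > 1L) for (t in 2:len) {
        x[t] <- sample.int(length(pool), 1L, prob = Ar[x[t - 1L], ])
      }
      path <- c(path, pool[x])
    }
  })
  path
}

#' Simulate observations along a state path
#'
#' Frame `t` is drawn from the multivariate normal of state `path[t]`
#' (state-specific mean and covariance), independently across frames given
#' the path.
#'
#' @param path integer per-frame state indices.
#' @param model a [GenerativeModel-class].
#' @param seed integer seed.
#' @param trSeconds TR recorded in the output object.
#' @param participantId participant label.
#' @return A [RoiTimeSeries-class].
#' @export
simulateObservations <- function(path, model, seed = 1L, trSeconds = 3,
                                 participantId = "p1") {
  if (any(path < 1L | path > model@K)) stop("path state outside 1..K")
  chols <- lapply(model@covs, function(S) {
    ch <- try(chol(S), silent = TRUE)
    if (inherits(ch, "try-error")) stop("state covariance is not positive-definite")
    ch
  })
  n <- length(path)
  X <- matrix(0, n, model@R)
  .withSeed(seed, {
    for (k in sort(unique(path))) {
      idx <- which(path == k)
      X[idx, ] <- .rmvnormChol(length(idx), model@means[k, ], chols[[k]])
    }
  })
  RoiTimeSeries(X, trSeconds = trSeconds, participantId = participantId)
}

#' Simulate a multi-participant synthetic night
#'
#' Generates one hypnogram, state path and observation matrix per
#' participant. Per-participant seeds are derived as `seed + participant - 1`
#' so a master seed fixes the whole dataset bit-for-bit.
#'
#' @param nParticipants number of participants (default 3).
#' @param model a [GenerativeModel-class] (default [defaultGenerativeModel()]).
#' @param spec a [HypnogramSpec-class] (default [defaultHypnogramSpec()]).
#' @param seed master seed.
#' @return A [SyntheticDataset-class].
#' @export
simulateSleepDataset <- function(nParticipants = 3L,
                                 model = defaultGenerativeModel(),
                                 spec = defaultHypnogramSpec(),
                                 seed = 1L) {
  sessions <- list(); paths <- list(); hyps <- list()
  for (p in seq_len(nParticipants)) {
    sp <- seed + p - 1L
    hyp <- simulateHypnogram(spec, seed = sp)
    path <- simulateStateSequence(hyp, model, seed = sp + 1000L)
    ts <- simulateObservations(path, model, seed = sp + 2000L,
                               trSeconds = spec@trSeconds,
                               participantId = sprintf("sim%02d", p))
    sessions[[p]] <- ts; paths[[p]] <- path; hyps[[p]] <- hyp
  }
  methods::new("SyntheticDataset", sessions = sessions, truePath = paths,
               hypnogram = hyps, model = model, seed = as.integer(seed))
}

#' Write a synthetic dataset to a directory
#'
#' One observation matrix + sidecar + hypnogram per participant, the
#' ground-truth model and the master seed as YAML. Round-trips losslessly
#' through [readDataset()].
#'
#' @param ds a [SyntheticDataset-class].
#' @param directory output directory (created if missing).
#' @return Invisibly, `directory`.
#' @export
writeDataset <- function(ds, directory) {
  methods::validObject(ds)
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) stop("cannot create directory: ", directory)
  for (p in seq_along(ds@sessions)) {
    base <- file.path(directory, sprintf("participant%02d", p))
    writeRoiMatrix(ds@sessions[[p]], paste0(base, "_obs.tsv"))
    writeHypnogram(ds@hypnogram[[p]], paste0(base, "_hypnogram.txt"))
    writeLines(as.character(ds@truePath[[p]]), paste0(base, "_truepath.txt"))
  }
  m <- ds@model
  yaml::write_yaml(list(
    seed = ds@seed,
    n_participants = length(ds@sessions),
    model = list(
      K = m@K, R = m@R,
      stage_pools = m@stagePools,
      A = apply(m@A, 1L, as.numeric, simplify = FALSE),
      pi = as.numeric(m@pi),
      means = apply(m@means, 1L, as.numeric, simplify = FALSE),
      covs = lapply(m@covs, function(S) apply(S, 1L, as.numeric, simplify = FALSE))
    )
  ), file.path(directory, "dataset.yaml"), precision = 17L)
  invisible(directory)
}

#' Read a synthetic dataset written by [writeDataset()]
#'
#' @param directory dataset directory.
#' @return A [SyntheticDataset-class].
#' @export
readDataset <- function(directory) {
  meta <- yaml::read_yaml(file.path(directory, "dataset.yaml"))
  m <- meta$model
  A <- do.call(rbind, lapply(m$A, as.numeric))
  pi <- as.numeric(m$pi)
  model <- methods::new("GenerativeModel",
    K = as.integer(m$K), R = as.integer(m$R),
    stagePools = lapply(m$stage_pools, as.integer),
    A = A / rowSums(A), # absorb last-ulp serialization drift
    pi = pi / sum(pi),
    means = do.call(rbind, lapply(m$means, as.numeric)),
    covs = lapply(m$covs, function(S) do.call(rbind, lapply(S, as.numeric))))
  sessions <- list(); paths <- list(); hyps <- list()
  for (p in seq_len(meta$n_participants)) {
    base <- file.path(directory, sprintf("participant%02d", p))
    sessions[[p]] <- readRoiMatrix(paste0(base, "_obs.tsv"))
    hyps[[p]] <- readHypnogram(paste0(base, "_hypnogram.txt"))
    paths[[p]] <- as.integer(readLines(paste0(base, "_truepath.txt")))
  }
  methods::new("SyntheticDataset", sessions = sessions, truePath = paths,
               hypnogram = hyps, model = model, seed = as.integer(meta$seed))
}
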