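# End-to-end orchestration: simulate/read -> standardize + concatenate ->
# PCA -> (scan K ->) fit -> state stats -> transition modules -> maps ->
# optionally apply the frozen model to a second night. Every artifact is a
# TSV stamped with the producing stage, a config hash and the master seed;
# rerunning the same config reproduces byte-identical numeric output.

#' PipelineConfig: validated pipeline configuration
#'
#' @slot config named list of validated settings.
#' @slot hash md5 hash of the normalized configuration.
#' @export
setClass("PipelineConfig",
         representation(config = "list", hash = "character"))

.knownKeys <- list(
  top = c("out_dir", "seed", "simulate", "inputs", "preprocessing", "hmm",
          "modularity", "apply", "networks"),
  simulate = c("n_participants", "n_channels", "k_true", "pools", "n_cycles",
               "dwell_dispersion", "self_transition", "separation",
               "tr_seconds"),
  inputs = c("observations", "hypnograms", "tr_seconds"),
  preprocessing = c("n_components"),
  hmm = c("k", "k_min", "k_max", "restarts", "tol", "max_iter"),
  modularity = c("symmetric"),
  apply = c("second_night", "observations", "hypnograms")
)

.checkUnknown <- function(x, allowed, where, problems) {
  bad <- setdiff(names(x), allowed)
  if (length(bad)) {
    problems <- c(problems, sprintf("unknown key(s) in %s: %s", where,
                                    paste(bad, collapse = ", ")))
  }
  problems
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list; checks every key before any
#' compute and reports all violations at once. Unknown keys are rejected.
#'
#' @param config path to a YAML file, or a named list.
#' @return A [PipelineConfig-class].
#' @export
validateConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    config <- yaml::read_yaml(config)
  }
  problems <- character()
  problems <- .checkUnknown(config, .knownKeys$top, "config", problems)
  if (is.null(config$out_dir)) problems <- c(problems, "out_dir is required")
  seed <- config$seed
  if (is.null(seed)) {
    config$seed <- 1L
  } else if (!is.numeric(seed) || length(seed) != 1L || seed < 0 ||
             seed != round(seed)) {
    problems <- c(problems, "seed must be a single non-negative integer")
  }
  if (is.null(config$simulate) && is.null(config$inputs)) {
    problems <- c(problems, "either 'simulate' or 'inputs' is required")
  }
  for (sec in c("simulate", "inputs", "preprocessing", "hmm", "modularity",
                "apply")) {
    if (!is.null(config[[sec]])) {
      problems <- .checkUnknown(config[[sec]], .knownKeys[[sec]], sec, problems)
    }
  }
  h <- config$hmm
  if (!is.null(h)) {
    hasK <- !is.null(h$k); hasRange <- !is.null(h$k_min) || !is.null(h$k_max)
    if (hasK && hasRange) problems <- c(problems, "hmm: give k or k_min/k_max, not both")
    if (hasRange && (is.null(h$k_min) || is.null(h$k_max))) {
      problems <- c(problems, "hmm: k_min and k_max must be given together")
    } else if (hasRange && h$k_min > h$k_max) {
      problems <- c(problems, "hmm: k_min must not exceed k_max")
    }
    if (!hasK && !hasRange) problems <- c(problems, "hmm: k or k_min/k_max required")
  } else {
    problems <- c(problems, "hmm section is required")
  }
  inp <- config$inputs
  if (!is.null(inp)) {
    if (is.null(inp$observations) || !length(inp$observations)) {
      problems <- c(problems, "inputs: observations paths required")
    }
    if (!is.null(inp$hypnograms) &&
        length(inp$hypnograms) != length(inp$observations)) {
      problems <- c(problems, "inputs: one hypnogram per observation file")
    }
  }
  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "))
  }
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  # hash excludes out_dir so the same analysis in a new directory matches
  norm <- config
  norm$out_dir <- NULL
  yaml::write_yaml(norm, tf)
  methods::new("PipelineConfig", config = config,
               hash = unname(tools::md5sum(tf)))
}

.writeTsv <- function(x, path, stage, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage=%s config_hash=%s seed=%d", stage, hash,
                     as.integer(seed)), con)
  x <- as.data.frame(x)
  fmt <- function(col) if (is.numeric(col)) sprintf("%.12g", col) else as.character(col)
  writeLines(paste(names(x), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(x, fmt), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

.log <- function(stage, ...) {
  message(format(Sys.time(), "%H:%M:%S"), " [", stage, "] ", ...)
}

# Stage labels of the retained (uncensored) frames, aligned with
# concatenateSessions' frame selection.
.concatLabels <- function(sessions, hypnograms) {
  unlist(lapply(seq_along(sessions), function(i) {
    s <- sessions[[i]]
    keep <- logical(nrow(s@data))
    for (r in seq_len(nrow(s@segments))) {
      fr <- (s@segments[r, 1L] + 1L):s@segments[r, 2L]
      keep[fr] <- s@censorMask[fr]
    }
    hypnograms[[i]][keep]
  }))
}

.defaultNetworks <- function(R) {
  paste0("net", ((seq_len(R) - 1L) %% 4L) + 1L)
}

.simulateNight <- function(sim, seed) {
  model <- defaultGenerativeModel(
    K = if (is.null(sim$k_true)) 6L else sim$k_true,
    R = if (is.null(sim$n_channels)) 20L else sim$n_channels,
    selfTransition = if (is.null(sim$self_transition)) 0.75 else sim$self_transition,
    separation = if (is.null(sim$separation)) 1.5 else sim$separation,
    pools = if (is.null(sim$pools)) "stage" else sim$pools)
  spec <- defaultHypnogramSpec(
    nCycles = if (is.null(sim$n_cycles)) 44L else sim$n_cycles,
    trSeconds = if (is.null(sim$tr_seconds)) 3 else sim$tr_seconds,
    dwellDispersion = if (is.null(sim$dwell_dispersion)) 0.3 else sim$dwell_dispersion)
  simulateSleepDataset(
    nParticipants = if (is.null(sim$n_participants)) 3L else sim$n_participants,
    model = model, spec = spec, seed = seed)
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order (simulate or read, standardize
#' and concatenate, PCA, order scan or fixed-K fit, state statistics,
#' transition modules, state maps, optional second-night application) and
#' writes the artifacts to `out_dir`. The master seed fans out to
#' stage-specific seeds by fixed offsets. Rerunning the same configuration
#' reproduces byte-identical numeric outputs.
#'
#' @param config a [PipelineConfig-class], a YAML path, or a named list
#'   (the latter two are passed through [validateConfig()]).
#' @return Invisibly, a list with the output directory and the main result
#'   objects (`pca`, `fit`, `summary`, `partition`, `scan`, `crossNight`).
#' @export
runPipeline <- function(config) {
  if (!methods::is(config, "PipelineConfig")) config <- validateConfig(config)
  cfg <- config@config
  hash <- config@hash
  seed <- as.integer(cfg$seed)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  # --- inputs -----------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$simulate)) {
    .log("simulate", "generating synthetic night (seed ", seed, ")")
    truth <- .simulateNight(cfg$simulate, seed)
    sessions <- truth@sessions
    hyps <- truth@hypnogram
    writeDataset(truth, file.path(out, "synthetic_night2"))
  } else {
    .log("ingest", "reading ", length(cfg$inputs$observations), " recording(s)")
    sessions <- lapply(cfg$inputs$observations, readRoiMatrix)
    hyps <- if (!is.null(cfg$inputs$hypnograms)) {
      lapply(cfg$inputs$hypnograms, readHypnogram)
    } else {
      lapply(sessions, function(s) rep("Undefined", nrow(s@data)))
    }
  }
  trSec <- sessions[[1L]]@trSeconds

  # --- preprocess -------------------------------------------------------
  .log("preprocess", "standardize + concatenate + PCA")
  sessions <- lapply(sessions, standardize)
  concat <- concatenateSessions(sessions)
  labels <- .concatLabels(sessions, hyps)
  nComp <- if (is.null(cfg$preprocessing$n_components)) 13L else {
    as.integer(cfg$preprocessing$n_components)
  }
  pca <- fitPca(concat, nComp)
  .log("preprocess", sprintf("%d components retain %.1f%% of variance",
                             nComp, 100 * explainedVariance(pca$model)))

  # --- model order / fit ------------------------------------------------
  h <- cfg$hmm
  restarts <- if (is.null(h$restarts)) 5L else as.integer(h$restarts)
  tol <- if (is.null(h$tol)) 1e-5 else h$tol
  maxIter <- if (is.null(h$max_iter)) 500L else as.integer(h$max_iter)
  scan <- NULL
  if (!is.null(h$k)) {
    chosenK <- as.integer(h$k)
  } else {
    .log("select-k", "scanning K = ", h$k_min, "..", h$k_max)
    scan <- scanOrders(pca$scores, seq.int(h$k_min, h$k_max),
                       segmentIndex = concat@segmentIndex, trSeconds = trSec,
                       stageLabels = labels, seed = seed + 100L,
                       nRestarts = restarts, maxIter = maxIter, tol = tol)
    chosenK <- scan@chosenK
    .writeTsv(data.frame(k = scan@kValues, free_energy = scan@freeEnergies,
                         max_fo = scan@maxFo, median_fo = scan@medianFo,
                         mean_lifetime_s = scan@meanLifetime,
                         wilks_lambda = scan@wilksLambda),
              file.path(out, "order_scan.tsv"), "select-k", hash, seed)
    .log("select-k", "first free-energy local minimum at K = ", chosenK)
  }
  .log("fit", "fitting K = ", chosenK, " (", restarts, " restarts)")
  fit <- fitHmm(pca$scores, chosenK, segmentIndex = concat@segmentIndex,
                maxIter = maxIter, tol = tol, nRestarts = restarts,
                seed = seed + 200L)

  # --- state statistics -------------------------------------------------
  summ <- stateSummary(fit@posteriors, labels, trSeconds = trSec)
  .writeTsv(cbind(data.frame(state = seq_len(chosenK), fo = summ@fo,
                             lifetime_s = summ@meanLifetimeS),
                  as.data.frame(summ@stageDist),
                  data.frame(wta_stage = summ@wtaStage)),
            file.path(out, "state_summary.tsv"), "stats", hash, seed)
  .writeTsv(as.data.frame(fit@model@A), file.path(out, "transition_matrix.tsv"),
            "fit", hash, seed)

  # --- transition modules -----------------------------------------------
  Wod <- offDiagonalNormalize(fit@model@A)
  part <- directedModularity(Wod, symmetric = isTRUE(cfg$modularity$symmetric))
  .log("modules", part@nModules, " modules, Q = ", sprintf("%.4f", part@q))
  .writeTsv(data.frame(state = seq_len(chosenK), module = part@assignment,
                       wta_stage = summ@wtaStage),
            file.path(out, "modules.tsv"), "modules", hash, seed)
  profile <- moduleStageProfile(part, summ@stageDist, summ@fo)
  .writeTsv(cbind(data.frame(module = seq_len(part@nModules)),
                  as.data.frame(profile)),
            file.path(out, "module_stage_profile.tsv"), "modules", hash, seed)

  # --- state maps -------------------------------------------------------
  proj <- projectToRoi(fit@model, pca$model)
  act <- relativeActivation(proj$means)
  .writeTsv(as.data.frame(act), file.path(out, "relative_activation.tsv"),
            "maps", hash, seed)
  fcs <- lapply(proj$covs, stateFc)
  sim <- fcSimilarity(fcs)
  .writeTsv(as.data.frame(sim), file.path(out, "fc_similarity.tsv"),
            "maps", hash, seed)
  roiNets <- if (!is.null(cfg$networks)) {
    nm <- readNetworkTable(cfg$networks)
    unname(nm[colnames(sessions[[1L]]@data)])
  } else {
    .defaultNetworks(ncol(sessions[[1L]]@data))
  }
  netFc <- networkAggregate(fcs[[1L]], roiNets)
  .writeTsv(as.data.frame(netFc), file.path(out, "network_fc_state1.tsv"),
            "maps", hash, seed)

  # --- second night (semi-supervised generalization) ---------------------
  crossNight <- NULL
  ap <- cfg$apply
  if (!is.null(ap)) {
    if (isTRUE(ap$second_night)) {
      if (is.null(truth)) stop("apply.second_night requires simulated inputs")
      .log("apply", "simulating and decoding the held-out night")
      night1 <- .simulateNight(cfg$simulate, seed + 5000L)
      s1 <- night1@sessions
      h1 <- night1@hypnogram
      writeDataset(night1, file.path(out, "synthetic_night1"))
    } else {
      .log("apply", "decoding the held-out night from disk")
      s1 <- lapply(ap$observations, readRoiMatrix)
      h1 <- lapply(ap$hypnograms, readHypnogram)
    }
    s1 <- lapply(s1, standardize)
    c1 <- concatenateSessions(s1)
    l1 <- .concatLabels(s1, h1)
    scores1 <- projectScores(pca$model, c1) # frozen training-night PCA
    post1 <- applyModel(scores1, fit@model, segmentIndex = c1@segmentIndex)
    dist1 <- stageDistribution(post1@viterbi, l1, K = chosenK)
    crossNight <- crossNightCorrelation(summ@stageDist, dist1)
    .log("apply", sprintf("cross-night stage-distribution r = %.3f", crossNight$r))
    .writeTsv(cbind(data.frame(state = seq_len(chosenK)), as.data.frame(dist1)),
              file.path(out, "night1_stage_distribution.tsv"), "apply", hash, seed)
    .writeTsv(data.frame(r = crossNight$r, p = crossNight$p),
              file.path(out, "cross_night.tsv"), "apply", hash, seed)
  }

  invisible(list(outDir = out, pca = pca$model, fit = fit, summary = summ,
                 partition = part, scan = scan, crossNight = crossNight,
                 configHash = hash))
}
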