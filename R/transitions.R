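# Transition-matrix post-processing and directed (Leicht-Newman) modularity.
#
# The displayed/analyzed matrix is the transition matrix with self-
# transitions removed and rows renormalized ("to other states"): raw rows are
# dominated by self-mass, which hides the between-state structure. Community
# structure is found by recursive spectral bisection of the symmetrized
# directed modularity matrix with deterministic Kernighan-Lin-style
# fine-tuning, stopping when no bisection increases Q.

#' Zero the diagonal and renormalize rows
#'
#' @param A K x K row-stochastic transition matrix, K >= 2.
#' @return K x K matrix with zero diagonal and rows summing to 1; a row with
#'   no off-diagonal mass is left all-zero with a warning.
#' @export
offDiagonalNormalize <- function(A) {
  A <- as.matrix(A)
  if (nrow(A) < 2L) stop("need at least two states")
  if (any(abs(rowSums(A) - 1) > 1e-8)) stop("A must be row-stochastic")
  diag(A) <- 0
  rs <- rowSums(A)
  if (any(rs == 0)) {
    warning("row(s) ", paste(which(rs == 0), collapse = ", "),
            " have no off-diagonal mass; left as zero rows", call. = FALSE)
  }
  A[rs > 0, ] <- A[rs > 0, , drop = FALSE] / rs[rs > 0]
  A
}

# Directed modularity of a partition: Q = (1/m) sum_{ij in same module}
# (W_ij - kout_i * kin_j / m). The single-module partition scores exactly 0.
.directedQ <- function(W, assignment) {
  m <- sum(W)
  B <- W - outer(rowSums(W), colSums(W)) / m
  same <- outer(assignment, assignment, "==")
  sum(B[same]) / m
}

# Deterministic Kernighan-Lin refinement of a bisection vector s on the
# (symmetric) subgraph modularity matrix Bg (objective s' Bg s). Each pass
# flips every node exactly once in best-gain order (ties and scans in
# ascending index), tracks the best intermediate state, and restarts from it
# while it improves. Escapes the shallow local optima a plain hill-climb
# gets stuck in, and can discover a split even from the trivial all-ones
# vector.
.fineTune <- function(Bg, s, tol = 1e-12) {
  n <- length(s)
  val <- as.numeric(t(s) %*% Bg %*% s)
  repeat {
    sw <- s
    moved <- rep(FALSE, n)
    cur <- val
    bestVal <- val
    bestState <- s
    for (step in seq_len(n)) {
      Ms <- as.numeric(Bg %*% sw)
      gains <- -4 * sw * (Ms - diag(Bg) * sw) # change in sw' Bg sw
      gains[moved] <- -Inf
      i <- which.max(gains) # ascending-index tie-break via which.max
      sw[i] <- -sw[i]
      moved[i] <- TRUE
      cur <- cur + gains[i]
      if (cur > bestVal + tol) {
        bestVal <- cur
        bestState <- sw
      }
    }
    if (bestVal > val + tol) {
      s <- bestState
      val <- bestVal
    } else {
      break
    }
  }
  s
}

#' Directed modularity partition of a transition graph
#'
#' Leicht-Newman directed modularity
#' `Q = (1/m) sum_ij (W_ij - kout_i kin_j / m) delta(c_i, c_j)`
#' maximized by recursive spectral bisection: the leading eigenvector of the
#' symmetrized modularity matrix `(B + B^T)/2` proposes each split, a
#' deterministic node-swap refinement improves it, and splitting stops when
#' no bisection increases Q (tolerance 1e-12). The number of modules is
#' emergent, not fixed in advance.
#'
#' @param W K x K nonnegative weight matrix (typically the off-diagonal-
#'   renormalized transition matrix), K >= 2.
#' @param symmetric if TRUE, symmetrize W first and use the undirected null
#'   model (fallback for near-symmetric graphs).
#' @return A [ModulePartition-class].
#' @export
directedModularity <- function(W, symmetric = FALSE) {
  W <- as.matrix(W)
  K <- nrow(W)
  if (K < 2L) stop("need at least two states")
  if (any(W < 0)) stop("W must be nonnegative")
  if (sum(W) <= 0) stop("W has no mass")
  if (symmetric) W <- .symmetrize(W)
  m <- sum(W)
  Bdir <- W - outer(rowSums(W), colSums(W)) / m
  B <- .symmetrize(Bdir)

  assignment <- rep(1L, K)
  repeat {
    improved <- FALSE
    for (mod in sort(unique(assignment))) {
      g <- which(assignment == mod)
      if (length(g) < 2L) next
      Bg <- B[g, g, drop = FALSE]
      Bg <- Bg - diag(rowSums(Bg)) # generalized modularity matrix
      ev <- eigen(Bg, symmetric = TRUE)
      # deterministic multi-start: the leading-eigenvector split plus every
      # single-node split, each refined by Kernighan-Lin; weak modular
      # structure (Q barely above the null) is invisible to the leading
      # eigenvector alone
      starts <- c(list(ifelse(ev$vectors[, 1L] >= 0, 1, -1)),
                  lapply(seq_along(g), function(i) {
                    s0 <- rep(1, length(g)); s0[i] <- -1; s0
                  }))
      s <- NULL; sval <- -Inf
      for (s0 in starts) {
        cand <- .fineTune(Bg, s0)
        cval <- as.numeric(t(cand) %*% Bg %*% cand)
        if (cval > sval + 1e-15) { sval <- cval; s <- cand }
      }
      if (length(unique(s)) < 2L) next
      dq <- sval / (2 * m)
      if (dq > 1e-12) {
        assignment[g[s < 0]] <- max(assignment) + 1L
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  # contiguous 1-based module ids in order of first appearance
  assignment <- as.integer(match(assignment, unique(assignment)))
  methods::new("ModulePartition", assignment = assignment,
               q = .directedQ(W, assignment),
               nModules = length(unique(assignment)))
}

#' Aggregate stage distributions over modules
#'
#' Occupancy-weighted average of the member states' stage-distribution rows,
#' renormalized, one row per module.
#'
#' @param partition a [ModulePartition-class].
#' @param stageDist K x 6 per-state stage distribution.
#' @param fo per-state fractional occupancy (weights); default equal.
#' @return nModules x 6 row-normalized matrix.
#' @export
moduleStageProfile <- function(partition, stageDist, fo = NULL) {
  K <- length(partition@assignment)
  if (nrow(stageDist) != K) stop("stageDist rows must match the state count")
  if (is.null(fo)) fo <- rep(1 / K, K)
  out <- matrix(0, partition@nModules, ncol(stageDist),
                dimnames = list(sprintf("module%d", seq_len(partition@nModules)),
                                colnames(stageDist)))
  for (mod in seq_len(partition@nModules)) {
    members <- which(partition@assignment == mod)
    if (!length(members)) stop("empty module ", mod)
    w <- fo[members]
    if (sum(w) <= 0) w <- rep(1, length(members))
    w <- w / sum(w)
    row <- colSums(stageDist[members, , drop = FALSE] * w)
    out[mod, ] <- row / sum(row)
  }
  out
}
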