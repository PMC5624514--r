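#' @import methods
#' @importFrom stats setNames
NULL

# ---------------------------------------------------------------------------
# ChainParams
# ---------------------------------------------------------------------------

#' Parameters of the hidden microstate chain
#'
#' Cells traverse a directed chain of `N + 1` molecular microstates
#' `0, 1, ..., N` at forward rate `qf` per hour (and optionally backward rate
#' `qb`). Contiguous blocks map to the observable macrostates: microstates
#' `0..nA` are ESC, `nA+1..nB` are EPI, and `nB+1..N` are NPC. State `N` is
#' absorbing, so `p_C(t)` is nondecreasing.
#'
#' @slot nA integer, last ESC microstate index.
#' @slot nB integer, last EPI microstate index.
#' @slot N integer, last microstate index (absorbing).
#' @slot qf forward transition rate per hour.
#' @slot qb backward transition rate per hour; `0` means irreversible.
#'
#' @export
setClass("ChainParams",
  representation(nA = "integer", nB = "integer", N = "integer",
                 qf = "numeric", qb = "numeric"))

setValidity("ChainParams", function(object) {
  msg <- character()
  if (length(object@nA) != 1L || length(object@nB) != 1L ||
      length(object@N) != 1L)
    msg <- c(msg, "nA, nB, N must be scalars")
  else {
    if (!(object@nA >= 0L && object@nA < object@nB && object@nB <= object@N))
      msg <- c(msg, "need 0 <= nA < nB <= N")
  }
  if (!is.finite(object@qf) || object@qf < 0)
    msg <- c(msg, "qf must be finite and >= 0")
  if (!is.finite(object@qb) || object@qb < 0)
    msg <- c(msg, "qb must be finite and >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct hidden-chain parameters
#'
#' @param nA last ESC microstate index (ESC block holds `nA + 1` microstates).
#' @param nB last EPI microstate index (EPI block holds `nB - nA`).
#' @param N last microstate index; defaults to `nB + 1` (the terminal NPC
#'   block collapsed to a single absorbing state, which is all that
#'   macrostate proportions can identify).
#' @param q forward transition rate per hour.
#' @param qb backward rate per hour (default 0, irreversible).
#' @return A [ChainParams-class] object.
#' @examples
#' ChainParams(nA = 7, nB = 18, q = 1 / 5.3)
#' @export
ChainParams <- function(nA, nB, N = nB + 1, q, qb = 0) {
  new("ChainParams", nA = as.integer(nA), nB = as.integer(nB),
      N = as.integer(N), qf = as.numeric(q), qb = as.numeric(qb))
}

#' Is the chain irreversible?
#' @param chain a [ChainParams-class] object.
#' @return `TRUE` when the backward rate is zero.
#' @export
isIrreversible <- function(chain) {
  stopifnot(is(chain, "ChainParams"))
  chain@qb == 0
}

setMethod("show", "ChainParams", function(object) {
  cat(sprintf(
    "ChainParams: %d microstates (ESC 0..%d | EPI %d..%d | NPC %d..%d)\n",
    object@N + 1L, object@nA, object@nA + 1L, object@nB,
    object@nB + 1L, object@N))
  if (isIrreversible(object))
    cat(sprintf("  irreversible, q = %.4g /hr (step time %.3g hr)\n",
                object@qf, 1 / object@qf))
  else
    cat(sprintf("  reversible, qf = %.4g, qb = %.4g /hr\n",
                object@qf, object@qb))
})

# ---------------------------------------------------------------------------
# MacrostateTrajectory
# ---------------------------------------------------------------------------

.MACROSTATES <- c("ESC", "EPI", "NPC")

#' Macrostate occupancy over time
#'
#' Observed or predicted proportions of cells in the ESC, EPI and NPC
#' macrostates at a set of experiment times, with optional bootstrap
#' confidence bounds.
#'
#' @slot time numeric vector of hours.
#' @slot props numeric matrix, one row per time, columns ESC/EPI/NPC,
#'   rows summing to 1.
#' @slot ci_lo,ci_hi optional matrices of bootstrap CI bounds (same shape as
#'   `props`, or 0-row when absent).
#'
#' @export
setClass("MacrostateTrajectory",
  representation(time = "numeric", props = "matrix",
                 ci_lo = "matrix", ci_hi = "matrix"))

setValidity("MacrostateTrajectory", function(object) {
  msg <- character()
  if (nrow(object@props) != length(object@time))
    msg <- c(msg, "props must have one row per time")
  if (!identical(colnames(object@props), .MACROSTATES))
    msg <- c(msg, "props columns must be ESC, EPI, NPC")
  if (any(object@props < -1e-9) || any(object@props > 1 + 1e-9))
    msg <- c(msg, "proportions must lie in [0, 1]")
  if (length(object@time) &&
      any(abs(rowSums(object@props) - 1) > 1e-6))
    msg <- c(msg, "proportions must sum to 1 at every time")
  if (is.unsorted(object@time, strictly = TRUE))
    msg <- c(msg, "time must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a macrostate trajectory
#'
#' @param time hours, strictly increasing.
#' @param props matrix (times x 3) of ESC/EPI/NPC proportions; rows must sum
#'   to 1.
#' @param ci_lo,ci_hi optional CI bound matrices.
#' @return A [MacrostateTrajectory-class] object.
#' @export
MacrostateTrajectory <- function(time, props, ci_lo = NULL, ci_hi = NULL) {
  props <- as.matrix(props)
  colnames(props) <- .MACROSTATES
  empty <- matrix(numeric(), 0, 3, dimnames = list(NULL, .MACROSTATES))
  fix <- function(m) {
    if (is.null(m)) return(empty)
    m <- as.matrix(m); colnames(m) <- .MACROSTATES; m
  }
  new("MacrostateTrajectory", time = as.numeric(time), props = props,
      ci_lo = fix(ci_lo), ci_hi = fix(ci_hi))
}

#' @describeIn MacrostateTrajectory sampling times in hours.
#' @param x a `MacrostateTrajectory`.
#' @export
trajTimes <- function(x) {
  stopifnot(is(x, "MacrostateTrajectory"))
  x@time
}

#' @describeIn MacrostateTrajectory proportion matrix (times x ESC/EPI/NPC).
#' @export
trajProps <- function(x) {
  stopifnot(is(x, "MacrostateTrajectory"))
  x@props
}

#' Convert a trajectory to a data.frame
#'
#' @param x a [MacrostateTrajectory-class].
#' @param ... ignored.
#' @return data.frame with columns `time_h`, `p_ESC`, `p_EPI`, `p_NPC` and,
#'   when bootstrap CIs are present, `lo_*`/`hi_*` columns.
#' @export
trajAsDataFrame <- function(x, ...) {
  stopifnot(is(x, "MacrostateTrajectory"))
  df <- data.frame(time_h = x@time,
                   p_ESC = x@props[, 1], p_EPI = x@props[, 2],
                   p_NPC = x@props[, 3])
  if (nrow(x@ci_lo)) {
    for (s in .MACROSTATES) {
      df[[paste0("lo_", s)]] <- x@ci_lo[, s]
      df[[paste0("hi_", s)]] <- x@ci_hi[, s]
    }
  }
  df
}

setMethod("show", "MacrostateTrajectory", function(object) {
  cat(sprintf("MacrostateTrajectory over %d times (%.3g-%.3g hr)%s\n",
              length(object@time), min(object@time), max(object@time),
              if (nrow(object@ci_lo)) " with bootstrap CIs" else ""))
  print(utils::head(trajAsDataFrame(object), 4))
  if (length(object@time) > 4) cat("  ...\n")
})

# ---------------------------------------------------------------------------
# FitResult
# ---------------------------------------------------------------------------

#' Result of fitting a transition model
#'
#' @slot model model identity string.
#' @slot par named list of fitted parameters.
#' @slot objective residual sum of squares `||y - f||^2` at the optimum
#'   (penalty excluded; see `lambda` and `penalty`).
#' @slot lambda regularization weight used (0 for continuous models).
#' @slot penalty value of the complexity penalty `nA + nB` (0 when not
#'   applicable).
#' @slot residuals numeric vector of residuals (data minus prediction).
#' @slot trajectory predicted [MacrostateTrajectory-class] on the data grid.
#' @slot path data.frame of the search path (per-restart objectives, or the
#'   lambda path).
#' @slot nPar number of free parameters, for parsimony comparisons.
#'
#' @export
setClass("FitResult",
  representation(model = "character", par = "list", objective = "numeric",
                 lambda = "numeric", penalty = "numeric",
                 residuals = "numeric", trajectory = "MacrostateTrajectory",
                 path = "data.frame", nPar = "numeric"))

setValidity("FitResult", function(object) {
  if (object@objective < 0) "objective must be >= 0" else TRUE
})

#' @describeIn FitResult fitted parameters as a named list.
#' @param x a `FitResult`.
#' @export
fittedParams <- function(x) {
  stopifnot(is(x, "FitResult"))
  x@par
}

#' @describeIn FitResult residual sum of squares at the optimum.
#' @export
fitObjective <- function(x) {
  stopifnot(is(x, "FitResult"))
  x@objective
}

#' @describeIn FitResult predicted trajectory on the data grid.
#' @export
fitTrajectory <- function(x) {
  stopifnot(is(x, "FitResult"))
  x@trajectory
}

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult [%s]: RSS = %.4g", object@model, object@objective))
  if (object@lambda > 0)
    cat(sprintf(" + %.3g x %g penalty", object@lambda, object@penalty))
  cat("\n  parameters:",
      paste(names(object@par),
            vapply(object@par, function(p) format(p, digits = 4), ""),
            sep = " = ", collapse = ", "), "\n")
})

# ---------------------------------------------------------------------------
# GeneNetwork
# ---------------------------------------------------------------------------

#' Undirected gene network from PID scores
#'
#' Pairwise confidence scores `c` in `[0, 2]` from the partial information
#' decomposition, with the retained top-quantile edges as an undirected
#' graph.
#'
#' @slot genes character vector of node names.
#' @slot scores data.frame with columns `gene_a`, `gene_b`, `u`, `c` for all
#'   pairs.
#' @slot graph igraph object over the retained edges.
#' @slot retention retained fraction of pairs.
#'
#' @export
setClass("GeneNetwork",
  representation(genes = "character", scores = "data.frame",
                 graph = "ANY", retention = "numeric"))

setValidity("GeneNetwork", function(object) {
  msg <- character()
  if (nrow(object@scores) &&
      (any(object@scores$c < -1e-9) || any(object@scores$c > 2 + 1e-9)))
    msg <- c(msg, "c scores must lie in [0, 2]")
  if (length(msg)) msg else TRUE
})

#' @describeIn GeneNetwork retained edges as a data.frame
#'   (`gene_a`, `gene_b`, `c_score`).
#' @param x a `GeneNetwork`.
#' @export
networkEdges <- function(x) {
  stopifnot(is(x, "GeneNetwork"))
  el <- igraph::as_data_frame(x@graph, what = "edges")
  data.frame(gene_a = el$from, gene_b = el$to, c_score = el$weight)
}

#' @describeIn GeneNetwork all pairwise scores (`gene_a`, `gene_b`, `u`, `c`).
#' @export
networkScores <- function(x) {
  stopifnot(is(x, "GeneNetwork"))
  x@scores
}

setMethod("show", "GeneNetwork", function(object) {
  cat(sprintf("GeneNetwork: %d genes, %d edges retained (top %.3g%% of %d pairs)\n",
              length(object@genes), igraph::ecount(object@graph),
              100 * object@retention, nrow(object@scores)))
})
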