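#' @importFrom stats rexp runif rnorm rpois
NULL

# run expr under a fixed RNG seed, restoring the caller's stream afterwards
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!is.finite(seed)) stop("seed must be a finite integer")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

#' Default experimental sampling grid
#'
#' Seven snapshot times (hours) matching the differentiation time course the
#' models are designed around.
#' @return numeric vector `c(0, 24, 48, 72, 96, 120, 168)`.
#' @export
defaultSampleTimes <- function() c(0, 24, 48, 72, 96, 120, 168)

# ---------------------------------------------------------------------------
# simulate_chain_cells
# ---------------------------------------------------------------------------

#' Simulate single cells on the microstate chain
#'
#' Each cell performs a continuous-time Markov jump process on microstates
#' `0..N` starting at 0 (all cells in the first microstate), with
#' exponential waiting times (exact simulation, no time discretization),
#' absorbing at `N`, recorded at the sample times. By default each sample
#' time receives an independent cohort of cells, mirroring a destructive
#' single-cell assay; set `longitudinal = TRUE` to follow the same cells
#' across all times.
#'
#' @param chain a [ChainParams-class] (irreversible or reversible).
#' @param sample_times hours, strictly increasing, nonnegative.
#' @param n_cells_per_time cells recorded per sample time (>= 1).
#' @param seed RNG seed.
#' @param longitudinal record the same cells at every time (TRUE) or an
#'   independent cohort per time (FALSE, default).
#' @return data.frame with columns `cell_id`, `time_h`, `microstate`,
#'   `macrostate` (ESC/EPI/NPC by the block partition).
#' @examples
#' simulateChainCells(ChainParams(7, 18, q = 1 / 5.3),
#'                    n_cells_per_time = 5, seed = 1)[1:5, ]
#' @export
simulateChainCells <- function(chain, sample_times = defaultSampleTimes(),
                               n_cells_per_time, seed = NULL,
                               longitudinal = FALSE) {
  stopifnot(is(chain, "ChainParams"))
  if (any(!is.finite(c(chain@qf, chain@qb))))
    stop("chain rates must be finite")
  sample_times <- .checkTimes(sample_times)
  if (n_cells_per_time < 1) stop("n_cells_per_time must be >= 1")
  .withSeed(seed, {
    if (longitudinal) {
      states <- .simulatePaths(chain, sample_times, n_cells_per_time)
      cell <- rep(seq_len(n_cells_per_time), times = length(sample_times))
      tim <- rep(sample_times, each = n_cells_per_time)
      ms <- as.vector(states)
    } else {
      ms <- unlist(lapply(sample_times, function(t0)
        .simulatePaths(chain, t0, n_cells_per_time)[, 1]))
      cell <- unlist(lapply(seq_along(sample_times), function(i)
        (i - 1L) * n_cells_per_time + seq_len(n_cells_per_time)))
      tim <- rep(sample_times, each = n_cells_per_time)
    }
    data.frame(
      cell_id = sprintf("cell_%05d_t%03d", cell, as.integer(tim)),
      time_h = tim,
      microstate = ms,
      macrostate = macrostateOf(chain, ms),
      stringsAsFactors = FALSE)
  })
}

# microstate of each of n cells at each sample time; returns cells x times
.simulatePaths <- function(chain, sample_times, n) {
  N <- chain@N
  if (isIrreversible(chain)) {
    if (chain@qf == 0)
      return(matrix(0L, n, length(sample_times)))
    # exact: jump times are cumulative exponential waits
    E <- matrix(rexp(n * N, rate = chain@qf), n, N)
    J <- E %*% upper.tri(diag(N), diag = TRUE)  # row cumsums
    vapply(sample_times,
           function(t0) as.integer(rowSums(J <= t0)),
           integer(n))
  } else {
    t_end <- max(sample_times)
    out <- matrix(NA_integer_, n, length(sample_times))
    for (i in seq_len(n)) {
      t <- 0; s <- 0L
      hist_t <- 0; hist_s <- 0L
      while (t < t_end && s < N) {
        rate <- chain@qf + if (s > 0L) chain@qb else 0
        t <- t + rexp(1, rate)
        if (t > t_end) break
        up <- runif(1) < chain@qf / rate
        s <- s + if (up) 1L else -1L
        hist_t <- c(hist_t, t); hist_s <- c(hist_s, s)
      }
      out[i, ] <- hist_s[findInterval(sample_times, hist_t)]
    }
    out
  }
}

#' Map microstate indices to macrostate labels
#'
#' @param chain a [ChainParams-class].
#' @param microstate integer vector of microstate indices.
#' @return factor-free character vector of ESC/EPI/NPC labels
#'   (`n <= nA` ESC, `nA < n <= nB` EPI, `n > nB` NPC).
#' @export
macrostateOf <- function(chain, microstate) {
  stopifnot(is(chain, "ChainParams"))
  ifelse(microstate <= chain@nA, "ESC",
         ifelse(microstate <= chain@nB, "EPI", "NPC"))
}

# ---------------------------------------------------------------------------
# emit_expression
# ---------------------------------------------------------------------------

#' Emission model linking macrostates to ET-scale expression
#'
#' Two-part model per gene: a macrostate-specific detection probability, and
#' a Gaussian level (clipped to `[0, et_max]`) for detected values;
#' undetected values are 0. This emulates the binarizable structure that
#' macrostate calling exploits; it is artifact plumbing, not a mechanistic
#' claim about how microstates produce expression.
#'
#' @param genes gene names.
#' @param expression_prob genes x 3 matrix (columns ESC, EPI, NPC) of
#'   detection probabilities in `[0, 1]`.
#' @param expressed_level_mean,expressed_level_sd ET-scale location and
#'   scale of detected values (per gene, recycled).
#' @param et_max cap of the ET scale (default 28).
#' @return an object of class `EmissionModel` (validated list).
#' @export
emissionModel <- function(genes, expression_prob,
                          expressed_level_mean = 14,
                          expressed_level_sd = 2, et_max = 28) {
  expression_prob <- as.matrix(expression_prob)
  if (nrow(expression_prob) != length(genes) || ncol(expression_prob) != 3)
    stop("expression_prob must be genes x 3 (ESC, EPI, NPC)")
  colnames(expression_prob) <- .MACROSTATES
  rownames(expression_prob) <- genes
  if (any(expression_prob < 0 | expression_prob > 1))
    stop("detection probabilities must lie in [0, 1]")
  m <- rep_len(expressed_level_mean, length(genes))
  s <- rep_len(expressed_level_sd, length(genes))
  if (any(m < 0 | m > et_max)) stop("expressed_level_mean outside [0, et_max]")
  structure(list(genes = genes, expression_prob = expression_prob,
                 expressed_level_mean = m, expressed_level_sd = s,
                 et_max = et_max),
            class = "EmissionModel")
}

#' Default emission model with macrostate marker blocks
#'
#' Twelve genes: four naive-pluripotency markers detected mostly in ESC,
#' four epiblast markers in EPI, four neural markers in NPC (detection 0.95
#' in the home state, 0.10 elsewhere). Marker names follow the genes that
#' characterize each state in mouse ESC neural differentiation.
#'
#' @param p_on,p_off detection probability in the home / other macrostates.
#' @return an `EmissionModel`.
#' @export
defaultEmissionModel <- function(p_on = 0.95, p_off = 0.10) {
  esc <- c("Pou5f1", "Nanog", "Esrrb", "Zfp42")
  epi <- c("Otx2", "Fgf5", "Dnmt3b", "Utf1")
  npc <- c("Nes", "Pax6", "Tubb3", "Cdh2")
  genes <- c(esc, epi, npc)
  prob <- matrix(p_off, length(genes), 3,
                 dimnames = list(genes, .MACROSTATES))
  prob[esc, "ESC"] <- p_on
  prob[epi, "EPI"] <- p_on
  prob[npc, "NPC"] <- p_on
  emissionModel(genes, prob)
}

#' Emit single-cell expression from macrostate labels
#'
#' @param trajectories data.frame from [simulateChainCells()].
#' @param model an `EmissionModel`.
#' @param seed RNG seed.
#' @return A [SummarizedExperiment::SummarizedExperiment] (genes x cells)
#'   with assay `ET` and colData `cell_id`, `time_h`, `true_macrostate`.
#' @export
emitExpression <- function(trajectories, model, seed = NULL) {
  stopifnot(inherits(model, "EmissionModel"))
  states <- trajectories$macrostate
  if (!all(states %in% .MACROSTATES))
    stop("unknown macrostate label(s): ",
         paste(unique(setdiff(states, .MACROSTATES)), collapse = ", "))
  nc <- nrow(trajectories); ng <- length(model$genes)
  .withSeed(seed, {
    p <- t(model$expression_prob[, states, drop = FALSE])  # cells x genes
    detected <- matrix(runif(nc * ng), nc, ng) < p
    level <- matrix(rnorm(nc * ng,
                          mean = rep(model$expressed_level_mean, each = nc),
                          sd = rep(model$expressed_level_sd, each = nc)),
                    nc, ng)
    et <- ifelse(detected, pmin(pmax(level, 0), model$et_max), 0)
    se <- SummarizedExperiment::SummarizedExperiment(
      assays = list(ET = t(et)),
      colData = S4Vectors::DataFrame(
        cell_id = trajectories$cell_id,
        time_h = trajectories$time_h,
        true_macrostate = states))
    rownames(se) <- model$genes
    colnames(se) <- make.unique(trajectories$cell_id)
    se
  })
}

# ---------------------------------------------------------------------------
# synth_bulk_timecourse
# ---------------------------------------------------------------------------

#' Synthetic bulk expression time course with planted drifting genes
#'
#' Non-drifting genes fluctuate around a constant baseline
#' (log2-expression scale); planted differentially expressed genes drift
#' monotonically away from their 0 hr value by `effect_size` over the
#' course (half up, half down). Feeds the cumulative-relative-expression
#' filter with known ground truth.
#'
#' @param n_genes total genes.
#' @param n_deg planted drifting genes (`<= n_genes`).
#' @param effect_size total log2 drift over the course.
#' @param sample_times timepoints in hours (first is the baseline).
#' @param noise_sd per-measurement Gaussian noise sd (log2 scale).
#' @param seed RNG seed.
#' @return list with `mat` (genes x timepoints matrix, columns named by
#'   time) and `truth` (data.frame `gene_id`, `is_deg`, `direction`).
#' @export
synthBulkTimecourse <- function(n_genes, n_deg, effect_size,
                                sample_times = defaultSampleTimes(),
                                noise_sd = 0.1, seed = NULL) {
  if (n_deg > n_genes) stop("n_deg must be <= n_genes")
  sample_times <- .checkTimes(sample_times)
  nt <- length(sample_times)
  .withSeed(seed, {
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    baseline <- rnorm(n_genes, mean = 8, sd = 2)
    direction <- rep(0, n_genes)
    if (n_deg > 0) {
      idx <- seq_len(n_deg)
      direction[idx] <- rep_len(c(1, -1), n_deg)
    }
    frac <- sample_times / max(sample_times)
    mat <- outer(baseline, rep(1, nt)) +
      outer(direction * effect_size, frac) +
      matrix(rnorm(n_genes * nt, sd = noise_sd), n_genes, nt)
    dimnames(mat) <- list(genes, paste0("t", sample_times))
    list(mat = mat,
         truth = data.frame(gene_id = genes,
                            is_deg = direction != 0,
                            direction = direction))
  })
}

# ---------------------------------------------------------------------------
# synth_reference_library
# ---------------------------------------------------------------------------

#' Synthetic reference lineage-profile library
#'
#' Builds a library of random expression profiles plus a test sample pair
#' (baseline and differentiated) whose change signature is concordant with
#' one designated profile: genes that go up in the test sample are high in
#' the match, genes that go down are low. A synthetic stand-in for a curated
#' library of tissue-specific expression patterns.
#'
#' @param n_profiles number of reference profiles (>= 2).
#' @param n_genes genes in the shared universe.
#' @param concordance strength with which the match profile follows the test
#'   signature (sd units).
#' @param seed RNG seed.
#' @return list with `profiles` (genes x profiles matrix), `test` and
#'   `baseline` (named numeric vectors), and `match` (the concordant
#'   profile's name).
#' @export
synthReferenceLibrary <- function(n_profiles, n_genes, concordance = 2,
                                  seed = NULL) {
  if (n_profiles < 2) stop("n_profiles must be >= 2")
  .withSeed(seed, {
    genes <- sprintf("gene_%04d", seq_len(n_genes))
    profiles <- matrix(rnorm(n_genes * n_profiles), n_genes, n_profiles,
                       dimnames = list(genes,
                                       sprintf("profile_%02d",
                                               seq_len(n_profiles))))
    baseline <- rnorm(n_genes, mean = 8)
    delta <- rnorm(n_genes)
    test <- baseline + delta
    profiles[, 1] <- concordance * scale(delta)[, 1] + rnorm(n_genes, sd = 0.5)
    names(test) <- names(baseline) <- genes
    list(profiles = profiles, test = test, baseline = baseline,
         match = colnames(profiles)[1])
  })
}
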