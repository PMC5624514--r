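#' @importFrom stats wilcox.test
NULL

#' Mediancentre of a cell population
#'
#' The point minimizing the total L1 distance to all cells (the
#' multivariate generalization of the univariate median). Because the L1
#' objective separates by coordinate, this is the coordinatewise median;
#' for even cell counts the midpoint of the two central values is used (a
#' canonical choice within the minimizing interval).
#'
#' @param x cells x genes numeric matrix.
#' @return numeric gene-space vector.
#' @export
mediancentre <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 1) stop("need at least one cell")
  apply(x, 2, median)
}

#' Multivariate dispersion about the mediancentre
#'
#' Each cell's dispersion is its L1 distance to the mediancentre; the
#' population dispersion `D` is their sum (the minimized value of the
#' mediancentre objective).
#'
#' @param x cells x genes numeric matrix.
#' @return list with `mediancentre`, `distances` (per cell) and `D`.
#' @export
dispersion <- function(x) {
  x <- as.matrix(x)
  M <- mediancentre(x)
  d <- rowSums(abs(sweep(x, 2, M)))
  list(mediancentre = M, distances = d, D = sum(d))
}

#' Compare dispersion between two cell groups
#'
#' Two-sided Wilcoxon rank-sum test on the per-cell dispersion values of
#' two populations.
#'
#' @param distA,distB per-cell dispersion values for the two groups.
#' @return two-sided p value.
#' @export
compareDispersion <- function(distA, distB) {
  if (length(distA) < 2 || length(distB) < 2)
    stop("each group needs at least 2 cells")
  wilcox.test(distA, distB, alternative = "two.sided")$p.value
}

#' Bayesian Blocks binning of a value set
#'
#' Optimal change-point binning by dynamic programming over the block
#' fitness `N_k (log N_k - log T_k)` (counts `N_k`, width `T_k`), with a
#' per-block prior penalty calibrated to a false-alarm probability `p0`:
#' `ncp_prior = 4 - log(73.53 p0 N^-0.478)`. Bin widths are not forced to
#' be uniform, so the binning adapts to multimodal expression.
#'
#' @param values numeric vector (>= 2 finite values for a nontrivial
#'   binning; constant input yields a single block).
#' @param p0 false-alarm probability of the block prior (default 0.05).
#' @return sorted numeric vector of block edges spanning the data range.
#' @export
bayesianBlocks <- function(values, p0 = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 2) stop("need at least 2 finite values")
  t <- sort(unique(values))
  n <- length(t)
  if (n == 1) return(c(t, t))          # constant input: one (degenerate) block
  wts <- as.numeric(table(sort(values)))   # multiplicity of each unique value
  edges <- c(t[1], (t[-n] + t[-1]) / 2, t[n])   # n + 1 candidate edges
  N <- sum(wts)
  ncp_prior <- 4 - log(73.53 * p0 * N^(-0.478))
  best <- numeric(n)
  last <- integer(n)
  cum_w <- c(0, cumsum(wts))
  for (R in seq_len(n)) {
    width <- edges[R + 1] - edges[seq_len(R)]
    width[width <= 0] <- .Machine$double.eps
    cnt <- cum_w[R + 1] - cum_w[seq_len(R)]
    fit <- cnt * (log(cnt) - log(width)) - ncp_prior +
      c(0, best[seq_len(R - 1)])
    last[R] <- which.max(fit)
    best[R] <- max(fit)
  }
  # backtrack the change points
  cp <- integer(0)
  idx <- n
  repeat {
    cp <- c(last[idx], cp)
    if (last[idx] == 1L) break
    idx <- last[idx] - 1L
  }
  sort(unique(c(edges[1], edges[cp[-1]], edges[n + 1])))
}

#' Shannon entropy over a binning
#'
#' Plug-in entropy (bits) of the bin-occupancy distribution, with the
#' convention `0 log 0 = 0`. Values on an edge fall in the lower bin;
#' values outside the edge span are clamped into the terminal bins.
#'
#' @param values numeric vector.
#' @param edges sorted bin edges (as from [bayesianBlocks()]).
#' @return entropy in bits, in `[0, log2(number of bins)]`.
#' @export
shannonEntropy <- function(values, edges) {
  values <- values[is.finite(values)]
  if (!length(values)) stop("no finite values")
  nb <- length(edges) - 1L
  if (nb < 1) return(0)
  bin <- findInterval(values, edges, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), nb)
  P <- tabulate(bin, nbins = nb) / length(values)
  P <- P[P > 0]
  -sum(P * log2(P))
}

#' Per-gene, per-timepoint expression entropy
#'
#' Discretizes each gene independently with Bayesian Blocks on the pooled
#' values (all cells, all times combined, so one binning serves the whole
#' course), then computes the Shannon entropy of bin occupancy per
#' timepoint. Genes with fewer than 2 distinct pooled values get entropy 0.
#'
#' @param se SummarizedExperiment with assay `ET` and colData `time_h`.
#' @param p0 Bayesian Blocks false-alarm probability.
#' @return list with `entropy` (genes x times matrix, bits), `mean_entropy`
#'   (per-time mean over genes) and `edges` (per-gene block edges).
#' @export
entropyByTime <- function(se, p0 = 0.05) {
  et <- SummarizedExperiment::assay(se, "ET")
  time_h <- SummarizedExperiment::colData(se)$time_h
  times <- sort(unique(time_h))
  H <- matrix(0, nrow(et), length(times),
              dimnames = list(rownames(et), paste0("t", times)))
  edges <- vector("list", nrow(et))
  names(edges) <- rownames(et)
  for (g in seq_len(nrow(et))) {
    v <- et[g, ]
    if (length(unique(v)) < 2) next
    e <- bayesianBlocks(v, p0 = p0)
    edges[[g]] <- e
    for (i in seq_along(times))
      H[g, i] <- shannonEntropy(v[time_h == times[i]], e)
  }
  list(entropy = H, mean_entropy = colMeans(H), edges = edges)
}

#' Per-timepoint population dispersion
#'
#' Mediancentre dispersion of the cell population at each sampling time,
#' with pairwise rank-sum comparisons of per-cell dispersion between
#' consecutive timepoints.
#'
#' @param se SummarizedExperiment with assay `ET` and colData `time_h`.
#' @return data.frame with `time_h`, `n_cells`, `D` (total dispersion),
#'   `mean_dist`, and `p_vs_prev` (two-sided rank-sum p against the
#'   previous timepoint; NA for the first).
#' @export
dispersionByTime <- function(se) {
  et <- SummarizedExperiment::assay(se, "ET")
  time_h <- SummarizedExperiment::colData(se)$time_h
  times <- sort(unique(time_h))
  prev <- NULL
  out <- lapply(times, function(t0) {
    d <- dispersion(t(et[, time_h == t0, drop = FALSE]))
    p <- if (is.null(prev) || length(prev) < 2 || length(d$distances) < 2)
      NA_real_ else compareDispersion(prev, d$distances)
    prev <<- d$distances
    data.frame(time_h = t0, n_cells = length(d$distances), D = d$D,
               mean_dist = mean(d$distances), p_vs_prev = p)
  })
  do.call(rbind, out)
}
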