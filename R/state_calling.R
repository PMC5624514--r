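#' @importFrom stats prcomp kmeans
NULL

#' Binarize an ET matrix
#'
#' Retains only whether each gene is detected: entries become 1 when
#' `ET > 0` and 0 otherwise. Discarding level information makes the
#' subsequent projection and clustering robust to level noise.
#'
#' @param x SummarizedExperiment with assay `ET`, or a numeric matrix.
#' @return 0/1 matrix with the dimensions of the input expression matrix.
#' @export
binarizeET <- function(x) {
  m <- if (is(x, "SummarizedExperiment"))
    SummarizedExperiment::assay(x, "ET") else as.matrix(x)
  (m > 0) + 0
}

#' Project cells onto the top two principal components
#'
#' Mean-centered PCA of the (binarized) cells x genes matrix, retaining the
#' top `n_components` variance axes. Each component is oriented so that its
#' largest-magnitude gene loading is positive, removing reflection
#' nondeterminism.
#'
#' @param binary genes x cells matrix (as from [binarizeET()]).
#' @param n_components components to retain (default 2).
#' @return list with `scores` (cells x components), `loadings`
#'   (genes x components) and `var_explained`.
#' @export
projectPca <- function(binary, n_components = 2) {
  x <- t(as.matrix(binary))            # cells x genes
  if (nrow(x) < 3) stop("need at least 3 cells")
  if (ncol(x) < 2) stop("need at least 2 genes")
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  if (length(pc$sdev) < n_components || pc$sdev[n_components] < 1e-12)
    stop("data rank below ", n_components, "; cannot project")
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  flip <- apply(rot, 2, function(v) sign(v[which.max(abs(v))]))
  rot <- sweep(rot, 2, flip, "*")
  scores <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2, flip, "*")
  list(scores = scores, loadings = rot,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}

#' Best-of-restarts k-means clustering
#'
#' @param scores cells x dims matrix.
#' @param k number of clusters.
#' @param n_restarts random restarts; the labelling with lowest
#'   within-cluster sum of squares wins.
#' @param seed RNG seed.
#' @return integer vector of cluster labels (1..k).
#' @export
clusterKmeans <- function(scores, k, n_restarts = 50, seed = NULL) {
  scores <- as.matrix(scores)
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(scores)) stop("k exceeds the number of cells")
  if (k == 1) return(rep(1L, nrow(scores)))
  .withSeed(seed, {
    km <- kmeans(scores, centers = k, nstart = n_restarts,
                 iter.max = 100)
    as.integer(km$cluster)
  })
}

#' GAP statistic for choosing the number of clusters
#'
#' For each `k`, compares the log within-cluster dispersion of the k-means
#' partition to its expectation under reference data drawn uniformly over
#' the principal-axis-aligned bounding box of the data. The selected `k` is
#' the smallest with `Gap(k) >= Gap(k+1) - SE(k+1)` (the 1-SE rule); the
#' full curve is returned so the elbow can be inspected.
#'
#' @param scores cells x dims matrix.
#' @param k_max largest `k` considered (default 10).
#' @param n_refs reference datasets per `k` (default 50).
#' @param seed RNG seed.
#' @param n_restarts k-means restarts per fit.
#' @return list with `k` (selected) and `curve` (data.frame `k`, `gap`,
#'   `se`).
#' @export
gapStatistic <- function(scores, k_max = 10, n_refs = 50, seed = NULL,
                         n_restarts = 25) {
  scores <- as.matrix(scores)
  if (k_max < 1) stop("k_max must be >= 1")
  if (nrow(unique(scores)) == 1)       # degenerate: all cells identical
    return(list(k = 1L,
                curve = data.frame(k = 1L, gap = 0, se = 0)))
  k_max <- min(k_max, nrow(unique(scores)) - 1L, nrow(scores) - 1L)
  .withSeed(seed, {
    kmfun <- function(x, k) {
      if (k == 1) list(cluster = rep(1L, nrow(x)))
      else kmeans(x, centers = k, nstart = n_restarts, iter.max = 100)
    }
    cg <- cluster::clusGap(scores, FUNcluster = kmfun, K.max = k_max,
                           B = n_refs, d.power = 2,
                           spaceH0 = "scaledPCA", verbose = FALSE)
    tab <- cg$Tab
    k <- cluster::maxSE(tab[, "gap"], tab[, "SE.sim"],
                        method = "Tibs2001SEmax")
    list(k = as.integer(k),
         curve = data.frame(k = seq_len(nrow(tab)),
                            gap = tab[, "gap"], se = tab[, "SE.sim"]))
  })
}

#' Default macrostate marker sets
#'
#' Naive-pluripotency markers identify the ESC cluster and neural markers
#' the NPC cluster; the remaining cluster is the epiblast-like state.
#' @return named list of gene-name vectors.
#' @export
defaultMarkerSets <- function() {
  list(ESC = c("Pou5f1", "Nanog", "Esrrb", "Zfp42", "Klf4", "Tbx3"),
       NPC = c("Nes", "Nestin", "Pax6", "Tubb3", "Cdh2"))
}

#' Map k-means clusters to ESC/EPI/NPC macrostates
#'
#' The cluster with the highest mean expression of naive-pluripotency
#' markers is labelled ESC, the one with the highest mean neural-marker
#' expression NPC, and the remaining cluster EPI. When the marker genes are
#' absent from the data, clusters are ordered by mean sampling time
#' (earliest ESC, latest NPC) with a warning.
#'
#' @param labels integer cluster labels (3 clusters).
#' @param se SummarizedExperiment with assay `ET` and colData `time_h`.
#' @param marker_sets list with `ESC` and `NPC` gene-name vectors.
#' @return named character vector: macrostate per cluster index.
#' @export
mapClustersToMacrostates <- function(labels, se,
                                     marker_sets = defaultMarkerSets()) {
  ks <- sort(unique(labels))
  if (length(ks) != 3) stop("macrostate mapping requires exactly 3 clusters")
  et <- SummarizedExperiment::assay(se, "ET")
  time_h <- SummarizedExperiment::colData(se)$time_h
  meanTime <- vapply(ks, function(k) mean(time_h[labels == k]), 0)
  markerMean <- function(genes) {
    genes <- intersect(genes, rownames(et))
    if (!length(genes)) return(NULL)
    vapply(ks, function(k)
      mean(et[genes, labels == k, drop = FALSE]), 0)
  }
  escScore <- markerMean(marker_sets$ESC)
  npcScore <- markerMean(marker_sets$NPC)
  mapping <- setNames(rep(NA_character_, 3), ks)
  if (is.null(escScore) || is.null(npcScore)) {
    warning("marker genes absent; ordering clusters by mean sampling time")
    ord <- order(meanTime)
    mapping[as.character(ks[ord])] <- .MACROSTATES
    return(mapping)
  }
  # ties broken toward the earliest mean sampling time for ESC,
  # latest for NPC
  esc <- ks[order(-escScore, meanTime)][1]
  npc <- ks[order(-npcScore, -meanTime)]
  npc <- npc[npc != esc][1]
  epi <- setdiff(ks, c(esc, npc))
  mapping[as.character(c(esc, epi, npc))] <- .MACROSTATES
  mapping
}

#' Call macrostates from single-cell snapshots
#'
#' Full state-calling pipeline: binarize, project onto the top two principal
#' components, choose the cluster number with the GAP statistic (or use a
#' fixed `k`), cluster with best-of-restarts k-means, and (for `k = 3`) map
#' clusters to ESC/EPI/NPC by marker expression.
#'
#' @param se SummarizedExperiment with assay `ET` and colData `time_h`.
#' @param k number of clusters, or `"auto"` to select via the GAP statistic.
#' @param marker_sets passed to [mapClustersToMacrostates()].
#' @param n_restarts,n_refs,seed tuning for k-means and the GAP reference
#'   draws.
#' @return object of class `StateCallResult`: list with `cluster` (per-cell
#'   labels), `macrostate` (per-cell ESC/EPI/NPC when `k = 3`), `mapping`,
#'   `scores` (PCA coordinates), `k`, and `gap` (curve or NULL).
#' @export
callStates <- function(se, k = "auto", marker_sets = defaultMarkerSets(),
                       n_restarts = 50, n_refs = 50, seed = NULL) {
  bin <- binarizeET(se)
  proj <- projectPca(bin)
  gap <- NULL
  if (identical(k, "auto")) {
    gap <- gapStatistic(proj$scores, seed = if (is.null(seed)) NULL
                        else seed + 1L, n_refs = n_refs)
    k <- gap$k
  }
  labels <- clusterKmeans(proj$scores, k, n_restarts = n_restarts,
                          seed = seed)
  macro <- NULL; mapping <- NULL
  if (k == 3) {
    mapping <- mapClustersToMacrostates(labels, se, marker_sets)
    macro <- unname(mapping[as.character(labels)])
  }
  structure(list(cluster = labels, macrostate = macro, mapping = mapping,
                 scores = proj$scores, k = k, gap = gap$curve),
            class = "StateCallResult")
}

#' @export
print.StateCallResult <- function(x, ...) {
  cat(sprintf("StateCallResult: %d cells, k = %d%s\n",
              length(x$cluster), x$k,
              if (!is.null(x$macrostate)) " (mapped to ESC/EPI/NPC)" else ""))
  invisible(x)
}

#' Macrostate proportions over time with bootstrap confidence intervals
#'
#' Per sample time, the fraction of cells called in each macrostate, with
#' percentile bootstrap confidence intervals obtained by resampling cells
#' with replacement within each timepoint.
#'
#' @param macrostate per-cell ESC/EPI/NPC labels.
#' @param time_h per-cell sampling times.
#' @param n_boot bootstrap resamples (default 1000; 0 skips the CIs).
#' @param conf confidence level (default 0.95).
#' @param seed RNG seed.
#' @return A [MacrostateTrajectory-class] with CI bounds.
#' @export
macrostateProportions <- function(macrostate, time_h, n_boot = 1000,
                                  conf = 0.95, seed = NULL) {
  stopifnot(length(macrostate) == length(time_h))
  if (!all(macrostate %in% .MACROSTATES))
    stop("macrostate labels must be ESC/EPI/NPC")
  times <- sort(unique(time_h))
  alpha <- (1 - conf) / 2
  propsOf <- function(lab) {
    tab <- table(factor(lab, levels = .MACROSTATES))
    as.numeric(tab) / length(lab)
  }
  .withSeed(seed, {
    props <- matrix(NA_real_, length(times), 3,
                    dimnames = list(NULL, .MACROSTATES))
    lo <- hi <- props
    for (i in seq_along(times)) {
      lab <- macrostate[time_h == times[i]]
      props[i, ] <- propsOf(lab)
      if (n_boot > 0) {
        boot <- vapply(seq_len(n_boot), function(b)
          propsOf(sample(lab, replace = TRUE)), numeric(3))
        lo[i, ] <- apply(boot, 1, quantile, alpha, type = 7)
        hi[i, ] <- apply(boot, 1, quantile, 1 - alpha, type = 7)
      }
    }
    if (n_boot > 0)
      MacrostateTrajectory(times, props, ci_lo = lo, ci_hi = hi)
    else MacrostateTrajectory(times, props)
  })
}
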