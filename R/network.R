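#' @importFrom stats quantile
NULL

# empirical joint distribution of discrete label vectors -> 3-d prob array
.jointCounts <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  table(x = x, y = y, z = z)
}

.mi <- function(pxy) {
  # mutual information (bits) of a 2-d joint probability matrix
  px <- rowSums(pxy); py <- colSums(pxy)
  idx <- pxy > 0
  sum(pxy[idx] * log2(pxy[idx] / outer(px, py)[idx]))
}

#' Partial information decomposition of a gene triplet
#'
#' Decomposes the mutual information two source variables `X`, `Y` carry
#' about a target `Z` into synergy, unique and redundant parts:
#' `I(X,Y;Z) = Synergy + Unique_X + Unique_Y + Redundancy`. Redundancy is
#' Williams-Beer `I_min`: the expectation over target states of the
#' smaller source-specific information,
#' `sum_z p(z) min_X sum_x p(x|z) log2(p(z|x)/p(z))`. All four terms are
#' nonnegative, and `Unique_X + Redundancy = I(X;Z)`.
#'
#' @param x,y discrete source label vectors (or `x` a 3-d contingency array
#'   of joint counts with dimensions X, Y, Z, in which case `y` and `z` are
#'   ignored).
#' @param z discrete target label vector.
#' @return list with `synergy`, `unique_x`, `unique_y`, `redundancy`,
#'   `mi_xz`, `mi_yz`, `mi_xyz` (all bits).
#' @examples
#' x <- rep(0:1, each = 2); y <- rep(0:1, 2)
#' pidDecompose(x, y, z = bitwXor(x, y))$synergy  # 1 bit
#' @export
pidDecompose <- function(x, y = NULL, z = NULL) {
  counts <- if (length(dim(x)) == 3) x else .jointCounts(x, y, z)
  if (sum(counts) == 0) stop("counts must not be all zero")
  p <- counts / sum(counts)
  pz <- apply(p, 3, sum)
  pxz <- apply(p, c(1, 3), sum)
  pyz <- apply(p, c(2, 3), sum)
  # specific information each source provides about target state z
  spec <- function(psz) {              # psz: source x target joint
    ps <- rowSums(psz)
    vapply(seq_along(pz), function(k) {
      if (pz[k] == 0) return(0)
      ps_given_z <- psz[, k] / pz[k]
      idx <- ps_given_z > 0
      sum(ps_given_z[idx] *
            (log2(psz[idx, k] / (ps[idx] * pz[k]))))
    }, 0)
  }
  red <- max(sum(pz * pmin(spec(pxz), spec(pyz))), 0)
  mi_xz <- .mi(pxz); mi_yz <- .mi(pyz)
  pxy_flat <- matrix(p, nrow = dim(p)[1] * dim(p)[2], ncol = dim(p)[3])
  mi_xyz <- .mi(pxy_flat)
  clamp <- function(v) max(v, 0)
  list(synergy = clamp(mi_xyz - mi_xz - mi_yz + red),
       unique_x = clamp(mi_xz - red),
       unique_y = clamp(mi_yz - red),
       redundancy = red,
       mi_xz = mi_xz, mi_yz = mi_yz, mi_xyz = mi_xyz)
}

#' Discretize expression per gene with Bayesian Blocks
#'
#' Each gene is binned independently on its pooled values (all cells
#' combined), yielding integer bin labels for information estimation.
#'
#' @param se SummarizedExperiment with assay `ET`, or a genes x cells
#'   matrix.
#' @param p0 Bayesian Blocks false-alarm probability.
#' @return list with `labels` (genes x cells integer matrix) and `edges`
#'   (per-gene block edges).
#' @export
discretizeExpression <- function(se, p0 = 0.05) {
  et <- if (is(se, "SummarizedExperiment"))
    SummarizedExperiment::assay(se, "ET") else as.matrix(se)
  labels <- matrix(1L, nrow(et), ncol(et), dimnames = dimnames(et))
  edges <- vector("list", nrow(et)); names(edges) <- rownames(et)
  for (g in seq_len(nrow(et))) {
    v <- et[g, ]
    if (length(unique(v)) < 2) { edges[[g]] <- range(v); next }
    e <- bayesianBlocks(v, p0 = p0)
    edges[[g]] <- e
    b <- findInterval(v, e, rightmost.closed = TRUE)
    labels[g, ] <- pmin(pmax(b, 1L), length(e) - 1L)
  }
  list(labels = labels, edges = edges)
}

#' Proportional unique contribution of a gene pair
#'
#' Sums, over every third gene `Y`, the ratio of the unique information to
#' the pair's mutual information, in both target directions:
#' `u_{X,Z} = sum_Y Unique_Y(Z;X) / I(X;Z) + sum_Y Unique_Y(X;Z) / I(X;Z)`.
#' High `u` means the dependency between `X` and `Z` is not explained away
#' by any other gene. Pairs with `I(X;Z) = 0` get `u = 0` (no dependency to
#' apportion).
#'
#' @param labels genes x cells integer label matrix (from
#'   [discretizeExpression()]).
#' @param i,j row indices (or names) of the pair.
#' @return scalar `u` in `[0, 2 (G - 2)]` for `G` genes.
#' @export
proportionalUnique <- function(labels, i, j) {
  G <- nrow(labels)
  if (G < 3) stop("need at least 3 genes")
  if (is.character(i)) i <- match(i, rownames(labels))
  if (is.character(j)) j <- match(j, rownames(labels))
  others <- setdiff(seq_len(G), c(i, j))
  # I(X;Z) does not depend on the third gene
  pxz <- .jointCounts(labels[i, ], labels[j, ], rep(1L, ncol(labels)))
  mi <- .mi(apply(pxz / sum(pxz), c(1, 2), sum))
  if (mi <= 0) return(0)
  u <- 0
  for (k in others) {
    # target Z = gene j, sources X = gene i, Y = gene k
    d1 <- pidDecompose(labels[i, ], labels[k, ], labels[j, ])
    # target X = gene i, sources Z = gene j, Y = gene k
    d2 <- pidDecompose(labels[j, ], labels[k, ], labels[i, ])
    u <- u + d1$unique_x / mi + d2$unique_x / mi
  }
  u
}

#' Pairwise PID confidence scores
#'
#' Computes the proportional unique contribution `u` for every gene pair,
#' then the confidence score `c = F_X(u_{X,Y}) + F_Y(u_{X,Y})`, where `F_X`
#' is the right-continuous empirical CDF over all `u` values involving gene
#' `X` (each pair's own value included). `c` lies in `[0, 2]`; the pair
#' that is maximal for both its genes scores 2.
#'
#' @param labels genes x cells integer label matrix.
#' @return data.frame with `gene_a`, `gene_b`, `u`, `c` for all pairs.
#' @export
pidScores <- function(labels) {
  G <- nrow(labels)
  if (G < 3) stop("need at least 3 genes")
  genes <- rownames(labels)
  if (is.null(genes)) genes <- paste0("g", seq_len(G))
  U <- matrix(0, G, G)
  pairs <- utils::combn(G, 2)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    U[i, j] <- U[j, i] <- proportionalUnique(labels, i, j)
  }
  cScore <- numeric(ncol(pairs)); uVal <- numeric(ncol(pairs))
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    ui <- U[i, -i]; uj <- U[j, -j]
    uVal[p] <- U[i, j]
    cScore[p] <- mean(ui <= U[i, j]) + mean(uj <= U[i, j])
  }
  data.frame(gene_a = genes[pairs[1, ]], gene_b = genes[pairs[2, ]],
             u = uVal, c = cScore, stringsAsFactors = FALSE)
}

#' Build the retained-edge gene network
#'
#' Keeps the top `retention` fraction of pairs by confidence score `c` as
#' undirected weighted edges. Ties at the cutoff are all included (and
#' reported via a message when they enlarge the edge set).
#'
#' @param scores data.frame from [pidScores()].
#' @param retention retained fraction of pairs (default 0.05).
#' @return A [GeneNetwork-class].
#' @export
buildNetwork <- function(scores, retention = 0.05) {
  if (!nrow(scores)) stop("need at least one pair")
  genes <- sort(unique(c(scores$gene_a, scores$gene_b)))
  k <- ceiling(retention * nrow(scores))
  thr <- sort(scores$c, decreasing = TRUE)[k]
  keep <- scores$c >= thr
  if (sum(keep) > k)
    message(sum(keep) - k, " tied pair(s) at the cutoff included")
  g <- igraph::graph_from_data_frame(
    data.frame(from = scores$gene_a[keep], to = scores$gene_b[keep],
               weight = scores$c[keep]),
    directed = FALSE,
    vertices = genes)
  new("GeneNetwork", genes = genes, scores = scores, graph = g,
      retention = retention)
}

#' Node degree and betweenness centrality
#'
#' Degree counts retained edges per gene; betweenness counts, for every
#' other node pair, the fraction of shortest paths (over unweighted
#' retained edges) passing through the gene. High degree marks hubs that
#' consolidate a state's program; high betweenness marks genes bridging
#' state-specific modules.
#'
#' @param network a [GeneNetwork-class].
#' @return data.frame with `gene`, `degree`, `betweenness`.
#' @export
nodeMetrics <- function(network) {
  stopifnot(is(network, "GeneNetwork"))
  g <- network@graph
  data.frame(gene = igraph::V(g)$name,
             degree = as.numeric(igraph::degree(g)),
             betweenness = as.numeric(
               igraph::betweenness(g, weights = NA, directed = FALSE)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Infer a PID gene network from single-cell expression
#'
#' Discretizes each gene with Bayesian Blocks (pooled across cells),
#' computes pairwise proportional-unique PID scores and retains the
#' top-quantile edges.
#'
#' @param se SummarizedExperiment with assay `ET` (or genes x cells
#'   matrix).
#' @param retention retained fraction of pairs.
#' @param p0 Bayesian Blocks false-alarm probability.
#' @param labels optional precomputed label matrix (skips discretization).
#' @return A [GeneNetwork-class].
#' @export
inferNetwork <- function(se, retention = 0.05, p0 = 0.05, labels = NULL) {
  if (is.null(labels)) labels <- discretizeExpression(se, p0 = p0)$labels
  buildNetwork(pidScores(labels), retention = retention)
}

#' Stage-specific networks and edge-score changes
#'
#' Infers one network from the early part of the course (cells called ESC
#' or EPI) and one from the late part (EPI or NPC), on the same gene
#' universe with a shared pooled discretization, and reports per-edge
#' confidence-score changes.
#'
#' @param se SummarizedExperiment with assay `ET`.
#' @param macrostate per-cell ESC/EPI/NPC calls.
#' @param retention retained fraction of pairs.
#' @param p0 Bayesian Blocks false-alarm probability.
#' @param min_cells warn when a stage has fewer cells than this.
#' @return list with `early`, `late` (both [GeneNetwork-class]) and `delta`
#'   (data.frame `gene_a`, `gene_b`, `c_early`, `c_late`, `delta_c`).
#' @export
stagedNetworks <- function(se, macrostate, retention = 0.05, p0 = 0.05,
                           min_cells = 20) {
  stopifnot(length(macrostate) == ncol(se))
  disc <- discretizeExpression(se, p0 = p0)
  early_idx <- macrostate %in% c("ESC", "EPI")
  late_idx <- macrostate %in% c("EPI", "NPC")
  for (nm in c("early", "late")) {
    nIdx <- sum(if (nm == "early") early_idx else late_idx)
    if (nIdx < min_cells)
      warning(nm, " stage has only ", nIdx, " cells")
  }
  early <- inferNetwork(se, retention,
                        labels = disc$labels[, early_idx, drop = FALSE])
  late <- inferNetwork(se, retention,
                       labels = disc$labels[, late_idx, drop = FALSE])
  es <- networkScores(early); ls <- networkScores(late)
  stopifnot(identical(es[, 1:2], ls[, 1:2]))
  delta <- data.frame(es[, c("gene_a", "gene_b")],
                      c_early = es$c, c_late = ls$c,
                      delta_c = ls$c - es$c)
  list(early = early, late = late, delta = delta)
}

#' Write a network as an edge-list TSV
#'
#' @param network a [GeneNetwork-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
writeNetworkTsv <- function(network, path) {
  utils::write.table(networkEdges(network), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
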