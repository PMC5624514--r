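#' @importFrom stats median quantile
NULL

#' Normalize raw qPCR CT values to the ET scale
#'
#' Cycling-threshold (CT) values are normalized per cell using the median CT
#' of the loading-control genes (default Actb and Gapdh): each cell's CTs
#' are shifted by (its control median - the global target, the median of all
#' cells' control medians). Normalized CT >= `ct_absent` is considered
#' absent, and the remainder is transformed linearly to
#' expression-threshold (ET) values, `ET = ct_absent - CT`, clipped to
#' `[0, ct_absent]` so 0 means absent and `ct_absent` maximal expression.
#'
#' @param ct genes x cells numeric matrix of raw CT values (larger = less
#'   expression; `NA` = undetected). Row names must include the controls.
#' @param time_h per-cell sampling times in hours.
#' @param loading_control_genes control gene names.
#' @param ct_absent absence threshold on the CT scale (default 28).
#' @param target CT value the per-cell control medians are aligned to. The
#'   default (`NULL`) uses the median of the per-cell control medians.
#'   Within a cell the transform is invariant to additive CT shifts that
#'   also shift the controls; with the data-driven default this holds up to
#'   the (robust) global target, and exactly for a fixed `target`.
#' @return list with `se` (a SummarizedExperiment, assay `ET`, colData
#'   `cell_id`, `time_h`), `control_ct` (per-cell raw control median), and
#'   `flagged` (logical, cells whose controls were all absent and which
#'   should be removed).
#' @export
normalizeCt <- function(ct, time_h,
                        loading_control_genes = c("Actb", "Gapdh"),
                        ct_absent = 28, target = NULL) {
  ct <- as.matrix(ct)
  if (!all(loading_control_genes %in% rownames(ct)))
    stop("loading-control genes missing from the CT matrix: ",
         paste(setdiff(loading_control_genes, rownames(ct)), collapse = ", "))
  if (length(time_h) != ncol(ct))
    stop("time_h must have one entry per cell")
  ctl <- ct[loading_control_genes, , drop = FALSE]
  ctl[ctl >= ct_absent] <- NA
  control_ct <- apply(ctl, 2, median, na.rm = TRUE)
  flagged <- !is.finite(control_ct)
  if (is.null(target)) target <- median(control_ct, na.rm = TRUE)
  shift <- control_ct - target
  norm_ct <- sweep(ct, 2, shift, "-")
  et <- ct_absent - norm_ct
  et[!is.finite(et) | norm_ct >= ct_absent] <- 0
  et <- pmin(pmax(et, 0), ct_absent)
  cid <- colnames(ct)
  if (is.null(cid)) cid <- sprintf("cell_%05d", seq_len(ncol(ct)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ET = et),
    colData = S4Vectors::DataFrame(cell_id = cid, time_h = time_h))
  colnames(se) <- cid
  list(se = se, control_ct = control_ct, flagged = flagged)
}

#' Filter cells by loading-control quality and total expression
#'
#' Removes cells whose loading-control CT exceeds `control_ct_max`
#' (low readings) and cells whose total ET lies outside
#' `[Q1 - k I, Q3 + k I]` of the per-cell-total distribution, where `Q1`,
#' `Q3` are quartiles and `I` the interquartile range (linear-interpolation
#' type-7 quantiles; `k = 2` by default).
#'
#' @param se SummarizedExperiment with assay `ET`.
#' @param control_ct per-cell raw control CT medians (from [normalizeCt()]).
#' @param control_ct_max maximum acceptable control CT (default 15).
#' @param iqr_mult IQR multiplier for the total-ET fence (default 2).
#' @return the filtered SummarizedExperiment; errors when nothing survives.
#' @export
filterCells <- function(se, control_ct, control_ct_max = 15, iqr_mult = 2) {
  et <- SummarizedExperiment::assay(se, "ET")
  if (length(control_ct) != ncol(et))
    stop("control_ct must have one entry per cell")
  bad_ctl <- !is.finite(control_ct) | control_ct > control_ct_max
  totals <- colSums(et)
  q <- quantile(totals, c(0.25, 0.75), type = 7, names = FALSE)
  I <- q[2] - q[1]
  bad_tot <- totals < q[1] - iqr_mult * I | totals > q[2] + iqr_mult * I
  keep <- !(bad_ctl | bad_tot)
  if (!any(keep)) stop("all cells removed by quality filters")
  se[, keep]
}

#' Drop genes absent in most cells
#'
#' Removes genes with no detected expression (`ET = 0`) in strictly more
#' than `absent_fraction` of cells.
#'
#' @param se SummarizedExperiment with assay `ET`.
#' @param absent_fraction absence-fraction threshold (default 0.8).
#' @return the filtered SummarizedExperiment.
#' @export
filterGenes <- function(se, absent_fraction = 0.8) {
  et <- SummarizedExperiment::assay(se, "ET")
  frac_absent <- rowMeans(et == 0)
  se[frac_absent <= absent_fraction, ]
}

#' Cumulative relative expression of a bulk time course
#'
#' Per gene, the sum over all non-baseline timepoints of the
#' log-scale expression change relative to the baseline (0 hr) column:
#' `CRE_g = sum_t (x_{g,t} - x_{g,0})`.
#'
#' @param bulk genes x timepoints numeric matrix (log-expression scale).
#' @param times numeric timepoints for the columns; defaults to parsing
#'   column names of the form `t<hours>`.
#' @param baseline_time baseline timepoint (default 0).
#' @return list with `cre` (named per-gene vector), quartiles `Q1`, `Q3`,
#'   and interquartile range `I` of the CRE distribution.
#' @export
computeCre <- function(bulk, times = NULL, baseline_time = 0) {
  bulk <- as.matrix(bulk)
  if (is.null(times)) {
    times <- suppressWarnings(as.numeric(sub("^t", "", colnames(bulk))))
    if (any(is.na(times)))
      stop("cannot parse timepoints from column names; pass `times`")
  }
  i0 <- which(times == baseline_time)
  if (length(i0) != 1)
    stop("baseline timepoint ", baseline_time, " not found exactly once")
  cre <- rowSums(bulk[, -i0, drop = FALSE] - bulk[, i0])
  q <- quantile(cre, c(0.25, 0.75), type = 7, names = FALSE)
  list(cre = cre, Q1 = q[1], Q3 = q[2], I = q[2] - q[1])
}

#' Call differentially expressed genes from CRE values
#'
#' A gene is differentially expressed when its cumulative relative
#' expression lies more than `iqr_mult` (default 3) interquartile ranges
#' above the third quartile (upregulated) or below the first quartile
#' (downregulated) of the pooled CRE distribution.
#'
#' @param cre_table output of [computeCre()].
#' @param iqr_mult IQR multiplier (default 3).
#' @return data.frame with `gene_id`, `cre`, `is_deg`, `direction`
#'   (+1 up, -1 down, 0 not differentially expressed).
#' @export
callDegs <- function(cre_table, iqr_mult = 3) {
  cre <- cre_table$cre
  if (length(cre) < 4) stop("need at least 4 genes to call DEGs")
  hi <- cre_table$Q3 + iqr_mult * cre_table$I
  lo <- cre_table$Q1 - iqr_mult * cre_table$I
  direction <- ifelse(cre > hi, 1L, ifelse(cre < lo, -1L, 0L))
  data.frame(gene_id = names(cre), cre = unname(cre),
             is_deg = direction != 0L, direction = direction,
             stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# TSV I/O
# ---------------------------------------------------------------------------

#' Write/read a single-cell ET table as TSV
#'
#' The on-disk layout is one row per cell with `cell_id`, `time_h`, an
#' optional `true_macrostate` column, and one column per gene.
#'
#' @param se SummarizedExperiment with assay `ET`.
#' @param path file path.
#' @return `writeCellsTsv` returns `path` invisibly; `readCellsTsv` returns
#'   a SummarizedExperiment.
#' @export
writeCellsTsv <- function(se, path) {
  et <- SummarizedExperiment::assay(se, "ET")
  cd <- SummarizedExperiment::colData(se)
  df <- data.frame(cell_id = cd$cell_id, time_h = cd$time_h,
                   check.names = FALSE)
  if ("true_macrostate" %in% colnames(cd))
    df$true_macrostate <- cd$true_macrostate
  df <- cbind(df, as.data.frame(t(et), check.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeCellsTsv
#' @export
readCellsTsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  meta <- intersect(c("cell_id", "time_h", "true_macrostate"), colnames(df))
  genes <- setdiff(colnames(df), meta)
  et <- t(as.matrix(df[, genes, drop = FALSE]))
  colnames(et) <- df$cell_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ET = et),
    colData = S4Vectors::DataFrame(df[, meta, drop = FALSE]))
  colnames(se) <- df$cell_id
  se
}
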