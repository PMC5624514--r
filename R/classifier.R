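#' Expression-change signature of a test sample
#'
#' Ranks genes by expression change versus the baseline and takes the top
#' `fraction` as the upregulated set and the bottom `fraction` as the
#' downregulated set. Rank-based, so any monotone transform of the changes
#' yields the same signature.
#'
#' @param test,baseline named numeric expression vectors on a common gene
#'   universe.
#' @param fraction tail fraction per set (default 0.05).
#' @return list with `up_genes`, `down_genes` and attribute `degenerate`
#'   (TRUE when the change vector is constant and the split is
#'   tie-arbitrary).
#' @export
makeSignature <- function(test, baseline, fraction = 0.05) {
  genes <- intersect(names(test), names(baseline))
  n <- length(genes)
  if (n < ceiling(1 / fraction))
    stop("need at least ", ceiling(1 / fraction), " shared genes")
  delta <- test[genes] - baseline[genes]
  k <- max(1L, floor(n * fraction))
  ord <- order(delta, decreasing = TRUE)
  sig <- list(up_genes = genes[ord[seq_len(k)]],
              down_genes = genes[rev(ord)[seq_len(k)]])
  attr(sig, "degenerate") <- length(unique(delta)) == 1
  if (attr(sig, "degenerate"))
    warning("constant change vector; signature split is tie-arbitrary")
  sig
}

# signed -log10 of the one-sided rank-sum p in the dominant direction
.signedLogP <- function(x, y) {
  if (!length(x) || !length(y)) return(NA_real_)
  exact <- length(x) <= 10 && length(y) <= 10 &&
    !anyDuplicated(c(x, y))
  pg <- suppressWarnings(
    wilcox.test(x, y, alternative = "greater", exact = exact)$p.value)
  pl <- suppressWarnings(
    wilcox.test(x, y, alternative = "less", exact = exact)$p.value)
  if (pg <= pl) -log10(max(pg, 1e-300)) else log10(max(pl, 1e-300))
}

#' Score a signature against one reference profile
#'
#' Compares the reference-profile expression values of the up-set against
#' those of the down-set with a Wilcoxon rank-sum test (exact for set sizes
#' up to 10, normal approximation otherwise). The score is the signed
#' `-log10` of the one-sided p value: positive when the up-set sits higher
#' in the reference (the reference resembles the direction of change),
#' negative when inverted, 0 when the reference does not separate the sets.
#' The `"background"` contrast instead compares each set against all other
#' genes in the reference and averages the two signed scores.
#'
#' @param signature list from [makeSignature()].
#' @param reference named numeric profile vector.
#' @param contrast `"updown"` (default) or `"background"`.
#' @return signed log10 p value (finite; p floored at 1e-300).
#' @export
scoreReference <- function(signature, reference,
                           contrast = c("updown", "background")) {
  contrast <- match.arg(contrast)
  up <- reference[intersect(signature$up_genes, names(reference))]
  down <- reference[intersect(signature$down_genes, names(reference))]
  n_missing <- length(signature$up_genes) + length(signature$down_genes) -
    length(up) - length(down)
  if (n_missing > 0)
    warning(n_missing, " signature gene(s) missing from the reference")
  if (!length(up) && !length(down)) {
    warning("no signature genes present in the reference; score undefined")
    return(NA_real_)
  }
  if (contrast == "updown") {
    if (length(unique(c(up, down))) == 1) return(0)
    .signedLogP(up, down)
  } else {
    bg <- reference[setdiff(names(reference),
                            c(signature$up_genes, signature$down_genes))]
    mean(c(.signedLogP(up, bg), -.signedLogP(down, bg)), na.rm = TRUE)
  }
}

#' Score a test time course against a reference library
#'
#' For each non-baseline timepoint, builds the change signature against the
#' baseline and scores it against every reference profile, yielding the
#' evolving similarity of the differentiating population to each lineage.
#'
#' @param timecourse genes x timepoints numeric matrix (column names are
#'   timepoint labels); the baseline is supplied separately.
#' @param baseline named numeric baseline (0 hr) profile.
#' @param references genes x profiles numeric matrix.
#' @param fraction signature tail fraction.
#' @param contrast passed to [scoreReference()].
#' @return profiles x timepoints matrix of signed log10 p scores.
#' @export
scoreLibrary <- function(timecourse, baseline, references, fraction = 0.05,
                         contrast = "updown") {
  timecourse <- as.matrix(timecourse)
  references <- as.matrix(references)
  out <- matrix(NA_real_, ncol(references), ncol(timecourse),
                dimnames = list(colnames(references), colnames(timecourse)))
  for (j in seq_len(ncol(timecourse))) {
    test <- setNames(timecourse[, j], rownames(timecourse))
    sig <- suppressWarnings(makeSignature(test, baseline, fraction))
    for (r in seq_len(ncol(references)))
      out[r, j] <- scoreReference(
        sig, setNames(references[, r], rownames(references)), contrast)
  }
  out
}

#' Top-scoring references at a timepoint
#'
#' @param scores profiles x timepoints matrix from [scoreLibrary()].
#' @param timepoint column name or index.
#' @param k number of profiles to return (most similar first).
#' @return data.frame with `profile`, `score`.
#' @export
topReferences <- function(scores, timepoint, k = 5) {
  v <- scores[, timepoint]
  ord <- order(v, decreasing = TRUE)[seq_len(min(k, length(v)))]
  data.frame(profile = rownames(scores)[ord], score = v[ord],
             row.names = NULL)
}
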