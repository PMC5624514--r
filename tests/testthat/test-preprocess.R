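# small raw CT fixture: 4 genes + 2 controls x 4 cells
rawCtFixture <- function() {
  ct <- rbind(
    Actb  = c(10, 12, 10, 11),
    Gapdh = c(10, 12, 10, 11),
    g1    = c(15, 17, 28, 20),
    g2    = c(20, 22, 30, NA),
    g3    = c(12, 14, 12, 13),
    g4    = c(27, 29, 27, 28))
  colnames(ct) <- paste0("c", 1:4)
  ct
}

test_that("CT normalization maps to ET with absence at the threshold", {
  res <- normalizeCt(rawCtFixture(), time_h = c(0, 0, 24, 24))
  et <- SummarizedExperiment::assay(res$se, "ET")
  # cell c2's controls sit 2 cycles above the target (median of 10,12,10,11
  # is 10.5): its CTs are shifted down by 1.5, cell c1 up by 0.5
  expect_equal(unname(et["g1", "c1"]), 28 - (15 + 0.5))
  expect_equal(unname(et["g1", "c2"]), 28 - (17 - 1.5))
  # normalized CT at/above 28 and missing values are absent
  expect_equal(unname(et["g2", "c3"]), 0)
  expect_equal(unname(et["g2", "c4"]), 0)
  expect_true(all(et >= 0 & et <= 28))
})

test_that("ET is invariant to per-cell additive CT shifts", {
  ct <- rawCtFixture()
  res0 <- normalizeCt(ct, time_h = rep(0, 4), target = 10)
  ct[, "c1"] <- ct[, "c1"] + 3       # shift one whole cell, controls included
  res1 <- normalizeCt(ct, time_h = rep(0, 4), target = 10)
  expect_equal(SummarizedExperiment::assay(res1$se, "ET")[, "c1"],
               SummarizedExperiment::assay(res0$se, "ET")[, "c1"])
})

test_that("cells with dead loading controls are flagged", {
  ct <- rawCtFixture()
  ct[c("Actb", "Gapdh"), "c3"] <- 28
  res <- normalizeCt(ct, time_h = rep(0, 4))
  expect_identical(unname(res$flagged), c(FALSE, FALSE, TRUE, FALSE))
})

test_that("cell filtering applies the control-CT and total-ET fences", {
  # identical cells: the ET fence removes nothing (I = 0, totals equal Q1)
  et <- matrix(5, 4, 10, dimnames = list(paste0("g", 1:4), paste0("c", 1:10)))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ET = et),
    colData = S4Vectors::DataFrame(cell_id = colnames(et),
                                   time_h = rep(0, 10)))
  expect_equal(ncol(filterCells(se, control_ct = rep(10, 10))), 10)

  # one cell with control CT 16 is removed, the rest kept
  ctl <- c(rep(10, 9), 16)
  expect_equal(colnames(filterCells(se, control_ct = ctl)),
               paste0("c", 1:9))

  # planted extreme-total outlier: brute-force quartiles say only it falls
  set.seed(1)
  et2 <- matrix(runif(20 * 20, 4, 6), 20, 20,
                dimnames = list(paste0("g", 1:20), paste0("c", 1:20)))
  et2[, 20] <- 28                    # planted extreme total
  totals <- colSums(et2)
  q <- quantile(totals, c(0.25, 0.75), type = 7)
  I <- q[2] - q[1]
  expect_true(totals[20] > q[2] + 2 * I)   # fixture sanity
  se2 <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ET = et2),
    colData = S4Vectors::DataFrame(cell_id = colnames(et2),
                                   time_h = rep(0, 20)))
  kept <- filterCells(se2, control_ct = rep(10, 20))
  expect_equal(ncol(kept), 19)
  expect_false("c20" %in% colnames(kept))
})

test_that("gene filtering uses a strict greater-than absence rule", {
  et <- matrix(1, 3, 100, dimnames = list(c("keep80", "drop81", "allon"),
                                          sprintf("c%03d", 1:100)))
  et["keep80", 1:80] <- 0
  et["drop81", 1:81] <- 0
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ET = et),
    colData = S4Vectors::DataFrame(cell_id = colnames(et),
                                   time_h = rep(0, 100)))
  out <- filterGenes(se)
  expect_true("keep80" %in% rownames(out))   # exactly 80% absent: retained
  expect_false("drop81" %in% rownames(out))
  # filtering only subsets; values are untouched
  expect_equal(SummarizedExperiment::assay(out, "ET")["allon", ],
               et["allon", ])
})

test_that("CRE is the summed change versus baseline and is antisymmetric", {
  mat <- rbind(flat = rep(5, 6),
               up = c(5, 6, 7, 8, 9, 10),
               dn = c(5, 4, 3, 2, 1, 0))
  colnames(mat) <- paste0("t", c(0, 24, 48, 72, 96, 120))
  cre <- computeCre(mat)
  expect_equal(unname(cre$cre["flat"]), 0)
  expect_equal(unname(cre$cre["up"]), 1 + 2 + 3 + 4 + 5)
  expect_equal(unname(cre$cre["dn"]), -15)
  expect_error(computeCre(mat, baseline_time = 999), "baseline")
})

test_that("DEG calling is an IQR outlier rule on the CRE distribution", {
  # all CREs equal: no DEGs
  matc <- matrix(5, 10, 3, dimnames = list(paste0("g", 1:10),
                                           paste0("t", c(0, 24, 48))))
  expect_equal(sum(callDegs(computeCre(matc))$is_deg), 0)

  # 100 tight-null genes plus one planted at Q3 + 4I: exactly one DEG-up,
  # verified against brute-force quantiles of the toy CRE vector
  set.seed(2)
  cre_vec <- rnorm(100)
  q <- quantile(cre_vec, c(0.25, 0.75), type = 7)
  planted <- q[2] + 4 * (q[2] - q[1])
  cre_all <- c(cre_vec, planted)
  names(cre_all) <- c(sprintf("g%03d", 1:100), "planted")
  qa <- quantile(cre_all, c(0.25, 0.75), type = 7, names = FALSE)
  tab <- list(cre = cre_all, Q1 = qa[1], Q3 = qa[2], I = qa[2] - qa[1])
  d <- callDegs(tab)
  expect_equal(sum(d$is_deg), 1)
  expect_equal(d$direction[d$gene_id == "planted"], 1L)
})

test_that("raising a gene's CRE never demotes it from DEG-up", {
  set.seed(3)
  base <- rnorm(50)
  qo <- quantile(base, c(0.25, 0.75), type = 7, names = FALSE)
  thresholds <- qo[2] + 3 * (qo[2] - qo[1])
  for (val in c(thresholds + 0.1, thresholds + 1, thresholds + 10)) {
    cre_all <- c(base, val)
    names(cre_all) <- c(sprintf("g%02d", 1:50), "gX")
    tab <- list(cre = cre_all, Q1 = qo[1], Q3 = qo[2], I = qo[2] - qo[1])
    expect_equal(callDegs(tab)$direction[51], 1L)
  }
})

test_that("single-cell TSV round-trips", {
  s <- simCalledStates(n_cells = 10, seed = 21)
  path <- tempfile(fileext = ".tsv")
  writeCellsTsv(s$se, path)
  back <- readCellsTsv(path)
  expect_equal(SummarizedExperiment::assay(back, "ET"),
               SummarizedExperiment::assay(s$se, "ET"))
  expect_equal(SummarizedExperiment::colData(back)$time_h, s$time_h)
})
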