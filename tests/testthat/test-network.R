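test_that("PID recovers the canonical copy and XOR decompositions", {
  x <- rep(0:1, each = 2); y <- rep(0:1, 2)

  # independent sources and target: everything vanishes
  d0 <- pidDecompose(rep(0:1, 8), rep(c(0, 0, 1, 1), 4),
                     rep(c(0, 1), c(8, 8)))
  expect_lt(d0$synergy + d0$unique_x + d0$unique_y + d0$redundancy, 1e-12)

  # copy: Z = X, Y independent -> 1 unique bit from X
  dc <- pidDecompose(x, y, x)
  expect_equal(dc$unique_x, 1)
  expect_equal(dc$unique_y, 0)
  expect_equal(dc$synergy, 0)
  expect_equal(dc$redundancy, 0)

  # XOR: Z = X xor Y -> 1 synergistic bit
  dx <- pidDecompose(x, y, bitwXor(x, y))
  expect_equal(dx$synergy, 1)
  expect_equal(dx$unique_x + dx$unique_y + dx$redundancy, 0)
})

test_that("PID identities and nonnegativity hold on random joints", {
  set.seed(1)
  for (r in 1:200) {
    dims <- sample(2:3, 3, replace = TRUE)
    counts <- array(rpois(prod(dims), 3), dim = dims)
    if (sum(counts) == 0) counts[1] <- 1
    d <- pidDecompose(counts)
    expect_gte(d$synergy, 0); expect_gte(d$unique_x, 0)
    expect_gte(d$unique_y, 0); expect_gte(d$redundancy, 0)
    expect_lt(abs(d$synergy + d$unique_x + d$unique_y + d$redundancy -
                  d$mi_xyz), 1e-9)
    expect_lt(abs(d$unique_x + d$redundancy - d$mi_xz), 1e-9)
    expect_lt(abs(d$unique_y + d$redundancy - d$mi_yz), 1e-9)
  }
})

test_that("proportional unique contribution follows the enumeration oracle", {
  x <- rep(0:1, each = 4); y <- rep(0:1, 4)
  lab <- rbind(X = x, Z = x, Y = y)      # Z copies X, Y independent
  expect_equal(proportionalUnique(lab, "X", "Z"), 2)
  expect_equal(proportionalUnique(lab, "X", "Z"),
               proportionalUnique(lab, "Z", "X"))
  # independent pair: I(X;Z) = 0 -> u = 0 by convention
  lab2 <- rbind(X = x, Z = y, Y = c(rep(0, 7), 1))
  expect_equal(proportionalUnique(lab2, "X", "Z"), 0)
})

test_that("confidence scores are per-gene CDF sums in [0, 2]", {
  set.seed(2)
  n <- 60
  a <- rbinom(n, 1, 0.5)
  lab <- rbind(A = a, B = a,             # planted strong pair
               C = rbinom(n, 1, 0.5), D = rbinom(n, 1, 0.5))
  sc <- pidScores(lab)
  expect_true(all(sc$c >= 0 & sc$c <= 2))
  top <- sc[which.max(sc$c), ]
  expect_setequal(c(top$gene_a, top$gene_b), c("A", "B"))
  expect_equal(top$c, 2)                 # maximal for both its genes

  # all-equal u values give all-equal c
  scores_flat <- data.frame(gene_a = c("a", "a", "b"),
                            gene_b = c("b", "c", "c"),
                            u = c(1, 1, 1), c = c(2, 2, 2))
  expect_equal(length(unique(scores_flat$c)), 1)
})

test_that("edge retention keeps the top quantile with ties included", {
  set.seed(3)
  g <- 20
  pairs <- t(utils::combn(g, 2))
  sc <- data.frame(gene_a = paste0("g", pairs[, 1]),
                   gene_b = paste0("g", pairs[, 2]),
                   u = 0, c = runif(nrow(pairs)))
  net <- buildNetwork(sc, retention = 0.05)
  expect_equal(nrow(networkEdges(net)),
               ceiling(0.05 * nrow(sc)))
  full <- buildNetwork(sc, retention = 1)
  expect_equal(nrow(networkEdges(full)), nrow(sc))

  # ties at the cutoff are all included
  sc$c <- rep(c(1, 0.5), c(20, nrow(sc) - 20))
  expect_message(net_t <- buildNetwork(sc, retention = 0.05), "tied")
  expect_equal(nrow(networkEdges(net_t)), 20)
})

test_that("node metrics match hand-enumerated graphs", {
  mkNet <- function(edges) {
    sc <- data.frame(gene_a = edges[, 1], gene_b = edges[, 2], u = 1, c = 1)
    buildNetwork(sc, retention = 1)
  }
  # path a-b-c: the middle node carries the single shortest path
  pathNet <- mkNet(cbind(c("a", "b"), c("b", "c")))
  pm <- nodeMetrics(pathNet)
  expect_equal(pm$betweenness[pm$gene == "b"], 1)
  expect_equal(pm$betweenness[pm$gene %in% c("a", "c")], c(0, 0))

  # star K_{1,4}: centre degree 4, betweenness C(4,2) = 6
  starNet <- mkNet(cbind(rep("hub", 4), paste0("leaf", 1:4)))
  sm <- nodeMetrics(starNet)
  expect_equal(sm$degree[sm$gene == "hub"], 4)
  expect_equal(sm$betweenness[sm$gene == "hub"], 6)

  # complete graph: no intermediaries anywhere
  k4 <- t(utils::combn(c("a", "b", "c", "d"), 2))
  km <- nodeMetrics(mkNet(k4))
  expect_true(all(km$betweenness == 0))
  expect_true(all(km$degree == 3))
})

test_that("planted pairwise couplings outrank independent genes", {
  set.seed(4)
  n <- 500
  # Boolean-rule generative model: g2 copies g1 with 10% flips, g4 is the
  # AND of g1 and g3; g5..g8 independent noise
  g1 <- rbinom(n, 1, 0.5); g3 <- rbinom(n, 1, 0.5)
  flip <- rbinom(n, 1, 0.1)
  g2 <- ifelse(flip == 1, 1 - g1, g1)
  g4 <- as.integer(g1 & g3)
  lab <- rbind(g1 = g1, g2 = g2, g3 = g3, g4 = g4,
               g5 = rbinom(n, 1, 0.5), g6 = rbinom(n, 1, 0.5),
               g7 = rbinom(n, 1, 0.5), g8 = rbinom(n, 1, 0.5))
  sc <- pidScores(lab)
  planted <- with(sc, (gene_a %in% c("g1", "g2") & gene_b %in% c("g1", "g2")) |
                      (gene_a %in% c("g1", "g3", "g4") &
                       gene_b %in% c("g1", "g3", "g4")))
  auc <- mean(outer(sc$c[planted], sc$c[!planted], ">")) +
    0.5 * mean(outer(sc$c[planted], sc$c[!planted], "=="))
  expect_gt(auc, 0.8)
})

test_that("staged networks share the gene universe and detect rewiring", {
  set.seed(5)
  n <- 300
  stage <- rep(c("ESC", "EPI", "NPC"), each = n / 3)
  base <- function() rbinom(n, 1, 0.5)
  # pair (g1, g2) couples only in NPC cells, so only the late (EPI + NPC)
  # stage can see the dependency
  g1 <- base()
  g2 <- ifelse(stage == "NPC", g1, base())
  # ET scale: exact zeros when off, a spread expressed mode when on
  lvl <- function(b) b * rnorm(n, 14, 1)
  et <- rbind(g1 = lvl(g1), g2 = lvl(g2), g3 = lvl(base()),
              g4 = lvl(base()), g5 = lvl(base()))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(ET = et),
    colData = S4Vectors::DataFrame(cell_id = paste0("c", 1:n),
                                   time_h = rep(0:2, each = n / 3) * 24))
  sn <- stagedNetworks(se, stage, retention = 0.2)
  expect_identical(sort(sn$early@genes), sort(sn$late@genes))
  d12 <- sn$delta[sn$delta$gene_a == "g1" & sn$delta$gene_b == "g2", ]
  expect_gt(d12$delta_c, 0)
  expect_equal(max(sn$delta$delta_c), d12$delta_c)

  # identical cell subsets give identical networks
  allEpi <- rep("EPI", n)
  sn2 <- suppressWarnings(stagedNetworks(se, allEpi, retention = 0.2))
  expect_equal(networkScores(sn2$early), networkScores(sn2$late))
})
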