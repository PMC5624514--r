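# shared fixtures: the reference chain used across tests and a compact
# simulate -> emit -> call-states wrapper

refChain <- function() ChainParams(nA = 7, nB = 18, q = 1 / 5.3)

simCalledStates <- function(chain = refChain(), n_cells = 100, seed = 1,
                            k = 3) {
  cells <- simulateChainCells(chain, n_cells_per_time = n_cells, seed = seed)
  se <- emitExpression(cells, defaultEmissionModel(), seed = seed + 1L)
  call <- callStates(se, k = k, seed = seed + 2L)
  list(cells = cells, se = se, call = call,
       time_h = SummarizedExperiment::colData(se)$time_h,
       truth = SummarizedExperiment::colData(se)$true_macrostate)
}

# three well-separated 2-d Gaussian blobs
threeBlobs <- function(n_per = 50, sep = 5, sd = 0.3, seed = 1) {
  set.seed(seed)
  rbind(matrix(rnorm(2 * n_per, 0, sd), ncol = 2),
        sweep(matrix(rnorm(2 * n_per, 0, sd), ncol = 2), 2, c(sep, 0), "+"),
        sweep(matrix(rnorm(2 * n_per, 0, sd), ncol = 2), 2, c(0, sep), "+"))
}
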