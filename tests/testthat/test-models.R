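tms <- defaultSampleTimes()

odeOracle <- function(derivFn, times, y0 = c(1, 0, 0)) {
  grid <- sort(unique(c(0, times)))
  sol <- deSolve::ode(y0, grid, derivFn, NULL, rtol = 1e-12, atol = 1e-14)
  sol[match(times, grid), -1, drop = FALSE]
}

test_that("first-order closed form matches dense ODE integration", {
  for (p in list(c(0.1, 0.02), c(0.03, 0.03), c(0.5, 0.01))) {
    fo <- solveFirstOrder(p[1], p[2], tms)
    ora <- odeOracle(function(t, y, parms)
      list(c(-p[1] * y[1], p[1] * y[1] - p[2] * y[2], p[2] * y[2])), tms)
    expect_lt(max(abs(trajProps(fo) - ora)), 1e-8)
  }
  expect_equal(unname(trajProps(solveFirstOrder(0.1, 0.2, c(0, 1)))[1, ]),
               c(1, 0, 0))
  # fast second step: EPI never accumulates
  expect_lt(max(trajProps(solveFirstOrder(0.1, 50, tms))[, "EPI"]), 0.01)
  expect_error(solveFirstOrder(-0.1, 0.2, tms), "nonnegative")
})

test_that("paracrine model reduces to first order and respects the switch", {
  fo <- solveFirstOrder(0.05, 0.02, tms)
  pc <- solveParacrine(0.05, 0.02, K = 1e8, times = tms, variant = "h1")
  expect_lt(max(abs(trajProps(pc) - trajProps(fo))), 1e-6)

  # ultrasensitive switch never opens while p_A > K
  t_short <- c(0, 2, 4, 6)           # p_A(6) = exp(-0.3) ~ 0.74 > K = 0.5?
  pu <- solveParacrine(0.01, 0.5, K = 0.5, times = t_short,
                       variant = "ultrasensitive")
  expect_true(all(trajProps(pu)[, "NPC"] < 1e-10))

  # h = 1 agrees with an independent stiff-solver oracle
  K <- 0.3
  ora <- odeOracle(function(t, y, parms) {
    g <- K / (K + y[1])
    list(c(-0.05 * y[1], 0.05 * y[1] - 0.04 * g * y[2], 0.04 * g * y[2]))
  }, tms)
  ph <- solveParacrine(0.05, 0.04, K = K, times = tms, variant = "h1")
  expect_lt(max(abs(trajProps(ph) - ora)), 1e-6)
})

test_that("microstate pmf is a delta at 0, normalized, and absorbing", {
  ch <- refChain()
  expect_equal(microstatePmf(ch, 0), c(1, rep(0, ch@N)))
  for (t0 in c(1, 10, 100, 5300)) {   # qt up to 1e3
    p <- microstatePmf(ch, t0)
    expect_true(all(p >= 0))
    expect_lt(abs(sum(p) - 1), 1e-12)
  }
  expect_gt(microstatePmf(ch, 1e5)[ch@N + 1], 1 - 1e-12)
  expect_error(microstatePmf(ChainParams(1, 2, q = 1, qb = 0.5), 1),
               "irreversible")
})

test_that("macrostate block sums equal the Poisson-CDF closed form", {
  set.seed(4)
  for (r in 1:10) {
    nA <- sample(0:10, 1); nB <- nA + sample(1:10, 1)
    ch <- ChainParams(nA, nB, N = nB + sample(1:3, 1), q = runif(1, 0.01, 1))
    tr <- trajProps(chainMacrostates(ch, tms))
    expect_true(all(tr >= 0 & tr <= 1))
    expect_lt(max(abs(rowSums(tr) - 1)), 1e-12)
    blocks <- t(vapply(tms, function(t0) {
      p <- microstatePmf(ch, t0)
      c(sum(p[1:(nA + 1)]), sum(p[(nA + 2):(nB + 1)]),
        sum(p[(nB + 2):(ch@N + 1)]))
    }, numeric(3)))
    expect_lt(max(abs(tr - blocks)), 1e-12)
  }
})

test_that("the nA=0, nB=1 chain reduces to first-order kinetics in ESC", {
  q <- 1 / 20
  ch <- ChainParams(0, 1, N = 3, q = q)
  tr <- trajProps(chainMacrostates(ch, tms))
  fo <- trajProps(solveFirstOrder(q, q, tms))
  expect_lt(max(abs(tr[, "ESC"] - fo[, "ESC"])), 1e-12)
  expect_lt(max(abs(tr[, "ESC"] - exp(-q * tms))), 1e-12)
})

test_that("reversible solver conserves probability and nests the chain", {
  # minimal chain N = 1: reversibility has no interior state to act on
  m <- solveReversible(ChainParams(0, 1, N = 1, q = 0.1, qb = 0.5),
                       c(0, 10, 50))
  expect_lt(max(abs(rowSums(m$pmf) - 1)), 1e-9)
  expect_lt(max(abs(m$pmf[, 1] - exp(-0.1 * c(0, 10, 50)))), 1e-8)

  ch <- refChain()
  rv <- solveReversible(ch, tms)
  expect_lt(max(abs(rowSums(rv$pmf) - 1)), 1e-9)
  expect_lt(max(abs(trajProps(rv$trajectory) -
                    trajProps(chainMacrostates(ch, tms)))), 1e-8)

  # backward flux slows macrostate progression at every time
  chr <- ChainParams(7, 18, q = 1 / 5.3, qb = 1 / 5.3)
  slow <- trajProps(solveReversible(chr, tms)$trajectory)
  fast <- trajProps(chainMacrostates(ch, tms))
  expect_true(all(slow[-1, "NPC"] <= fast[-1, "NPC"] + 1e-9))
  expect_true(all(slow[-1, "ESC"] >= fast[-1, "ESC"] - 1e-9))
})

test_that("conveyor belt advects the initial density forward", {
  # zero speed freezes the proportions
  cv0 <- trajProps(solveConveyor(0.3, 1, 0, init = "gaussian", mu = 0,
                                 sigma = 0.5, times = tms))
  expect_true(all(apply(cv0, 2, function(col) length(unique(col)) == 1)))

  # uniform init loses ESC mass linearly until exhausted
  cvU <- trajProps(solveConveyor(a = 1, b = 2, c_speed = 0.02,
                                 init = "uniform", L = 1, times = tms))
  dA <- diff(cvU[, "ESC"]) / diff(tms)
  live <- cvU[-1, "ESC"] > 0          # before exhaustion the slope is constant
  expect_lt(diff(range(dA[live])), 1e-9)
  expect_true(all(diff(cvU[, "ESC"]) <= 1e-12))

  # gaussian init matches quadrature of the advected density
  mu <- -0.2; sigma <- 0.4; a <- 0.5; cc <- 0.01
  cvG <- trajProps(solveConveyor(a = a, b = 1.5, c_speed = cc,
                                 init = "gaussian", mu = mu, sigma = sigma,
                                 times = tms))
  quad <- vapply(tms, function(t0)
    integrate(function(x) dnorm(x - cc * t0, mu, sigma), -Inf, a,
              rel.tol = 1e-12)$value, 0)
  expect_lt(max(abs(cvG[, "ESC"] - quad)), 1e-9)
})

test_that("wait times are Erlang with block-size shape", {
  ch <- refChain()
  wt <- waitTimeDistribution(ch, "ESC")
  expect_equal(wt$shape, 8)
  expect_equal(wt$mean, 8 * 5.3)
  wtB <- waitTimeDistribution(ch, "EPI")
  expect_equal(wtB$shape, 11)

  # shape-1 blocks are exponential
  ch1 <- ChainParams(0, 1, N = 2, q = 0.2)
  w1 <- waitTimeDistribution(ch1, "ESC")
  tau <- seq(0, 30, by = 0.5)
  expect_equal(w1$cdf(tau), 1 - exp(-0.2 * tau))

  # CDF matches simulated first-passage times out of the ESC block
  set.seed(11)
  n <- 1e4
  fp <- rowSums(matrix(rexp(n * 8, rate = ch@qf), n, 8))
  ks <- max(abs(wt$cdf(sort(fp)) - seq_len(n) / n))
  expect_lt(ks, 0.02)
})

test_that("the ESC exit hazard increases with age for nA >= 1", {
  wt <- waitTimeDistribution(refChain(), "ESC")
  tau <- seq(1, 120, by = 1)
  expect_true(all(diff(wt$hazard(tau)) > -1e-12))
  expect_gt(wt$hazard(100) / wt$hazard(5), 5)
  # memoryless contrast: a single-microstate block has constant hazard
  w1 <- waitTimeDistribution(ChainParams(0, 1, q = 0.2), "ESC")
  expect_lt(diff(range(w1$hazard(tau))), 1e-9)
})

test_that("age-structured transport reproduces the chain marginals", {
  ch <- refChain()
  sol <- solveAgeStructured(ch, t_max = 168, dt = 0.05)
  ana <- trajProps(chainMacrostates(ch, c(0, sol$time[-1])))
  expect_lt(max(abs(trajProps(sol$trajectory) - ana)), 1e-3)
  expect_lt(sol$conservation_error, 1e-3)

  # nA=0, nB=1: macrostates and microstates coincide; first-order limit
  ch1 <- ChainParams(0, 1, N = 2, q = 1 / 20)
  sol1 <- solveAgeStructured(ch1, t_max = 168, dt = 0.05)
  fo <- trajProps(solveFirstOrder(1 / 20, 1 / 20, c(0, sol1$time[-1])))
  expect_lt(max(abs(trajProps(sol1$trajectory) - fo)), 1e-3)

  # coarse grids degrade gracefully with a warning
  expect_warning(solveAgeStructured(ch, t_max = 168, dt = 5, tol = 1e-6),
                 "grid too coarse")
})

test_that("NPC occupancy is nondecreasing for every model", {
  dense <- seq(0, 168, by = 1)
  mods <- list(
    solveFirstOrder(0.05, 0.02, dense),
    solveParacrine(0.05, 0.02, K = 0.3, times = dense, variant = "h1"),
    chainMacrostates(refChain(), dense),
    solveReversible(ChainParams(7, 18, q = 0.2, qb = 0.02), dense)$trajectory,
    solveConveyor(0.5, 1.5, 0.02, init = "gaussian", mu = 0, sigma = 0.5,
                  times = dense))
  for (m in mods)
    expect_true(all(diff(trajProps(m)[, "NPC"]) >= -1e-9))
})
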