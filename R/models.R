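#' @importFrom stats dpois ppois dgamma pgamma punif pnorm dnorm qnorm
NULL

.checkTimes <- function(times) {
  if (!is.numeric(times) || any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and nonnegative")
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing")
  times
}

# ---------------------------------------------------------------------------
# First-order kinetics
# ---------------------------------------------------------------------------

#' First-order (memoryless) transition kinetics
#'
#' Closed-form solution of the linear cascade
#' `dpA/dt = -q1 pA`, `dpB/dt = q1 pA - q2 pB`, `dpC/dt = q2 pB`
#' with all cells starting in ESC (`pA(0) = 1`). Each macrostate exit is a
#' single exponential step, so the exit hazard is constant: this is the
#' memoryless null model the microstate chain is compared against.
#'
#' @param q1,q2 transition rates per hour (ESC to EPI, EPI to NPC).
#' @param times sampling times in hours, strictly increasing.
#' @return A [MacrostateTrajectory-class].
#' @examples
#' solveFirstOrder(0.03, 0.02, times = c(0, 24, 48, 72, 96, 120, 168))
#' @export
solveFirstOrder <- function(q1, q2, times) {
  if (!is.finite(q1) || !is.finite(q2) || q1 < 0 || q2 < 0)
    stop("rates must be finite and nonnegative")
  times <- .checkTimes(times)
  pA <- exp(-q1 * times)
  # q1 == q2 handled by the limiting form q1 t exp(-q1 t)
  pB <- if (isTRUE(all.equal(q1, q2))) {
    q1 * times * exp(-q1 * times)
  } else {
    q1 / (q2 - q1) * (exp(-q1 * times) - exp(-q2 * times))
  }
  pC <- pmax(0, 1 - pA - pB)
  MacrostateTrajectory(times, cbind(ESC = pA, EPI = pB, NPC = pC))
}

# ---------------------------------------------------------------------------
# Paracrine feedback
# ---------------------------------------------------------------------------

#' Paracrine-feedback transition model
#'
#' Residual undifferentiated ESCs inhibit the EPI-to-NPC transition: the
#' second rate is scaled by `K^h / (K^h + pA^h)`. Three variants: `h1`
#' (non-cooperative, Hill coefficient 1), `free_h` (h supplied), and
#' `ultrasensitive` (the `h -> Inf` limit, where the B-to-C flux switches on
#' only once `pA < K`).
#'
#' @param q1,q2 rates per hour.
#' @param K inhibition threshold on the ESC proportion scale.
#' @param h Hill coefficient (used by `free_h`; `h1` forces 1).
#' @param times hours, strictly increasing.
#' @param variant one of `"h1"`, `"free_h"`, `"ultrasensitive"`.
#' @return A [MacrostateTrajectory-class].
#' @export
solveParacrine <- function(q1, q2, K, h = 1, times,
                           variant = c("h1", "free_h", "ultrasensitive")) {
  variant <- match.arg(variant)
  if (any(!is.finite(c(q1, q2, K))) || q1 < 0 || q2 < 0 || K <= 0)
    stop("need finite q1, q2 >= 0 and K > 0")
  times <- .checkTimes(times)
  if (variant == "h1") h <- 1
  if (variant == "free_h" && (!is.finite(h) || h < 1))
    stop("free_h variant needs finite h >= 1")
  inhib <- if (variant == "ultrasensitive") {
    function(pA) as.numeric(pA < K)     # Heaviside H(K - pA)
  } else {
    function(pA) K^h / (K^h + pA^h)
  }
  deriv <- function(t, y, parms) {
    g <- inhib(y[1])
    list(c(-q1 * y[1],
           q1 * y[1] - q2 * g * y[2],
           q2 * g * y[2]))
  }
  grid <- sort(unique(c(0, times)))
  sol <- deSolve::ode(c(1, 0, 0), grid, deriv, NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE solver failed: istate = ", attr(sol, "istate")[1])
  p <- sol[match(times, grid), 2:4, drop = FALSE]
  p <- pmin(pmax(p, 0), 1)
  p <- p / rowSums(p)
  MacrostateTrajectory(times, cbind(ESC = p[, 1], EPI = p[, 2], NPC = p[, 3]))
}

# ---------------------------------------------------------------------------
# Irreversible microstate chain (analytic)
# ---------------------------------------------------------------------------

#' Microstate occupancy of the irreversible chain
#'
#' For the irreversible chain the microscopic dynamics are a homogeneous
#' Poisson process: `p_n(t)` is the Poisson pmf at `n` with mean `qt` for
#' `n < N`, and the absorbing state collects the remaining mass,
#' `p_N = 1 - sum_{n<N} p_n`. Computed in log space so large `qt` stays
#' stable.
#'
#' @param chain a [ChainParams-class]; must be irreversible.
#' @param t time in hours (scalar).
#' @return numeric vector of length `N + 1` summing to 1.
#' @export
microstatePmf <- function(chain, t) {
  stopifnot(is(chain, "ChainParams"))
  if (!isIrreversible(chain))
    stop("microstatePmf requires an irreversible chain; use solveReversible")
  if (!is.finite(t) || t < 0) stop("t must be finite and nonnegative")
  N <- chain@N
  mu <- chain@qf * t
  p <- dpois(0:(N - 1), mu)
  # absorbing mass via the upper tail, not 1 - sum(p), for accuracy
  c(p, ppois(N - 1, mu, lower.tail = FALSE))
}

#' Macrostate proportions of the irreversible chain
#'
#' Analytic solution: `p_A(t) = F(nA, qt)`, `p_B(t) = F(nB, qt) - F(nA, qt)`,
#' `p_C(t) = 1 - F(nB, qt)` where `F` is the Poisson cumulative distribution
#' function with mean `qt` (block sums of the microstate pmf).
#'
#' @param chain a [ChainParams-class]; must be irreversible.
#' @param times hours, strictly increasing.
#' @return A [MacrostateTrajectory-class].
#' @examples
#' chainMacrostates(ChainParams(7, 18, q = 1 / 5.3),
#'                  times = c(0, 24, 48, 72, 96, 120, 168))
#' @export
chainMacrostates <- function(chain, times) {
  stopifnot(is(chain, "ChainParams"))
  if (!isIrreversible(chain))
    stop("chainMacrostates requires an irreversible chain")
  times <- .checkTimes(times)
  mu <- chain@qf * times
  FA <- ppois(chain@nA, mu)
  FB <- ppois(chain@nB, mu)
  MacrostateTrajectory(times,
    cbind(ESC = FA, EPI = FB - FA, NPC = 1 - FB))
}

# ---------------------------------------------------------------------------
# Reversible chain (numerical)
# ---------------------------------------------------------------------------

#' Reversible microstate chain
#'
#' Birth-death chain on microstates `0..N` with forward rate `qf` and
#' backward rate `qb`, reflecting at 0 and absorbing at N, solved
#' numerically with a probability-conserving generator. At `qb = 0` this
#' reduces exactly to the irreversible Poisson-process solution.
#'
#' @param chain a [ChainParams-class] (any `qb >= 0`).
#' @param times hours, strictly increasing.
#' @return list with `trajectory` (a [MacrostateTrajectory-class]) and `pmf`
#'   (times x microstates occupancy matrix).
#' @export
solveReversible <- function(chain, times) {
  stopifnot(is(chain, "ChainParams"))
  times <- .checkTimes(times)
  N <- chain@N; qf <- chain@qf; qb <- chain@qb
  n <- N + 1L
  # generator Q (columns sum to 0): dp/dt = Q p
  Q <- matrix(0, n, n)
  for (i in 0:(N - 1)) {                 # forward i -> i+1
    Q[i + 1L, i + 1L] <- Q[i + 1L, i + 1L] - qf
    Q[i + 2L, i + 1L] <- Q[i + 2L, i + 1L] + qf
  }
  if (N >= 2) for (i in 1:(N - 1)) {     # backward i -> i-1 (N absorbing)
    Q[i + 1L, i + 1L] <- Q[i + 1L, i + 1L] - qb
    Q[i, i + 1L] <- Q[i, i + 1L] + qb
  }
  deriv <- function(t, y, parms) list(as.vector(Q %*% y))
  grid <- sort(unique(c(0, times)))
  y0 <- c(1, rep(0, N))
  sol <- deSolve::ode(y0, grid, deriv, NULL, method = "lsoda",
                      rtol = 1e-11, atol = 1e-13)
  pmf <- sol[match(times, grid), -1, drop = FALSE]
  colnames(pmf) <- paste0("n", 0:N)
  pA <- rowSums(pmf[, 1:(chain@nA + 1L), drop = FALSE])
  pB <- rowSums(pmf[, (chain@nA + 2L):(chain@nB + 1L), drop = FALSE])
  pC <- if (chain@nB + 2L > n) rep(0, nrow(pmf))   # empty NPC block (nB = N)
  else rowSums(pmf[, (chain@nB + 2L):n, drop = FALSE])
  s <- pA + pB + pC
  traj <- MacrostateTrajectory(times,
    cbind(ESC = pA / s, EPI = pB / s, NPC = pC / s))
  list(trajectory = traj, pmf = pmf)
}

# ---------------------------------------------------------------------------
# Conveyor belt
# ---------------------------------------------------------------------------

#' Deterministic conveyor-belt model
#'
#' Differentiation progresses along a continuous 1-D reaction coordinate at
#' constant speed: initial population variability `f_0(x)` is advected
#' forward, `f_t(x) = f_0(x - c t)`, and macrostates are emitted by position
#' (`x <= a` ESC, `a < x <= b` EPI, `x > b` NPC). All cell-cell variability
#' is present at time 0 and propagates deterministically.
#'
#' @param a,b macrostate boundaries, `a < b`.
#' @param c_speed advection speed (coordinate units per hour, `>= 0`).
#' @param init `"uniform"` (on `[-L, a]`, the bounded-domain equilibrium) or
#'   `"gaussian"` (mean `mu`, sd `sigma`, the mean-reverting equilibrium).
#' @param L domain half-width for the uniform initial condition (`-L < a`).
#' @param mu,sigma Gaussian initial-condition location and scale.
#' @param times hours, strictly increasing.
#' @return A [MacrostateTrajectory-class].
#' @export
solveConveyor <- function(a, b, c_speed, init = c("uniform", "gaussian"),
                          L = NULL, mu = NULL, sigma = NULL, times) {
  init <- match.arg(init)
  if (!is.finite(c_speed) || c_speed < 0) stop("c_speed must be >= 0")
  if (!(a < b)) stop("need a < b")
  times <- .checkTimes(times)
  F0 <- switch(init,
    uniform = {
      if (is.null(L) || !(-L < a)) stop("uniform init needs L with -L < a")
      function(x) punif(x, min = -L, max = a)
    },
    gaussian = {
      if (is.null(mu) || is.null(sigma) || sigma <= 0)
        stop("gaussian init needs mu and sigma > 0")
      function(x) pnorm(x, mean = mu, sd = sigma)
    })
  # forward advection: F_t(x) = F_0(x - c t)
  FA <- F0(a - c_speed * times)
  FB <- F0(b - c_speed * times)
  MacrostateTrajectory(times,
    cbind(ESC = FA, EPI = FB - FA, NPC = 1 - FB))
}

# ---------------------------------------------------------------------------
# Erlang wait times
# ---------------------------------------------------------------------------

#' Macrostate residence-time distribution
#'
#' The wait time in a macrostate block of the irreversible chain is the sum
#' of the exponential step times of its microstates, hence Erlang with shape
#' equal to the block size (ESC: `nA + 1`, EPI: `nB - nA`) and rate `q`.
#' Mean residence is `shape / q`. The increasing Erlang hazard (for shape
#' > 1) is the memory signature: exit probability grows with time already
#' spent in the macrostate, unlike the constant-hazard first-order model.
#'
#' @param chain a [ChainParams-class]; must be irreversible.
#' @param macrostate `"ESC"` or `"EPI"`.
#' @return list with `shape`, `rate`, `mean` (hours), and functions `pdf`,
#'   `cdf`, `survival`, `hazard` of residence time `tau`.
#' @examples
#' wt <- waitTimeDistribution(ChainParams(7, 18, q = 1 / 5.3), "ESC")
#' wt$mean  # 8 microstates x 5.3 hr = 42.4 hr
#' @export
waitTimeDistribution <- function(chain, macrostate = c("ESC", "EPI")) {
  stopifnot(is(chain, "ChainParams"))
  if (!isIrreversible(chain))
    stop("wait times are Erlang only for the irreversible chain")
  macrostate <- match.arg(macrostate)
  shape <- if (macrostate == "ESC") chain@nA + 1L else chain@nB - chain@nA
  rate <- chain@qf
  list(shape = shape, rate = rate, mean = shape / rate,
       pdf = function(tau) dgamma(tau, shape = shape, rate = rate),
       cdf = function(tau) pgamma(tau, shape = shape, rate = rate),
       survival = function(tau)
         pgamma(tau, shape = shape, rate = rate, lower.tail = FALSE),
       hazard = function(tau) {
         h <- exp(dgamma(tau, shape = shape, rate = rate, log = TRUE) -
                  pgamma(tau, shape = shape, rate = rate,
                         lower.tail = FALSE, log.p = TRUE))
         # deep in the survival tail the ratio overflows; Erlang hazard
         # saturates at the step rate
         h[!is.finite(h)] <- rate
         pmin(h, rate)
       })
}

# ---------------------------------------------------------------------------
# Age-structured macroscopic formulation
# ---------------------------------------------------------------------------

#' Age-structured macroscopic dynamics of the chain
#'
#' Reformulates the irreversible chain at the macrostate level: densities
#' `rho_A(t, tau)`, `rho_B(t, tau)`, `rho_C(t, tau)` over macrostate age
#' `tau` are transported along characteristics (`tau` advances with `t`)
#' and depleted at the Erlang hazard of the block's residence-time
#' distribution. Marginals over `tau` reproduce [chainMacrostates()] up to
#' quadrature error on the grid. The `tau`-dependent hazard is what makes
#' the macroscopic process non-Markov.
#'
#' @param chain a [ChainParams-class]; must be irreversible.
#' @param t_max horizon in hours.
#' @param dt grid step in hours for both `t` and `tau` (trapezoidal
#'   quadrature; marginal error is O(dt^2)).
#' @param tol warn when `|p_A + p_B + p_C - 1|` exceeds this anywhere.
#' @return list with `time`, `tau`, densities `rho_A` (survival mass carried
#'   on the `tau = t` characteristic, stored as a vector), `rho_B`, `rho_C`
#'   (time x tau matrices), and `trajectory` (a
#'   [MacrostateTrajectory-class] of the marginals).
#' @export
solveAgeStructured <- function(chain, t_max = 168, dt = 0.1, tol = 1e-3) {
  stopifnot(is(chain, "ChainParams"))
  if (!isIrreversible(chain))
    stop("age-structured formulation requires an irreversible chain")
  tgrid <- seq(0, t_max, by = dt)
  nt <- length(tgrid)
  wA <- waitTimeDistribution(chain, "ESC")
  wB <- waitTimeDistribution(chain, "EPI")
  # A: all cells enter at t = 0, so rho_A(t, tau) = S_A(t) delta(tau - t)
  sA <- wA$survival(tgrid)
  # flux out of A at time s (entry flux into B at age 0)
  bIn <- wA$pdf(tgrid)
  sB <- wB$survival(tgrid)
  fB <- wB$pdf(tgrid)
  # trapezoid weights on the tau grid
  tw <- function(k) {
    if (k == 1) return(0)               # zero-width tau interval at t = 0
    c(dt / 2, rep(dt, k - 2), dt / 2)
  }
  # rho_B(t_i, tau_j) = bIn(t_i - tau_j) * S_B(tau_j), tau_j <= t_i
  rhoB <- matrix(0, nt, nt)
  # exit flux from B at time s: integral of bIn(s - tau) f_B(tau) d tau
  cIn <- numeric(nt)
  pB <- numeric(nt)
  for (i in seq_len(nt)) {
    j <- seq_len(i)
    row <- bIn[i - j + 1L] * sB[j]
    rhoB[i, j] <- row
    w <- tw(i)
    pB[i] <- sum(w * row)
    cIn[i] <- sum(w * bIn[i - j + 1L] * fB[j])
  }
  # C is absorbing: rho_C(t, tau) = cIn(t - tau); p_C = cumulative entry
  rhoC <- matrix(0, nt, nt)
  pC <- numeric(nt)
  acc <- 0
  for (i in seq_len(nt)) {
    j <- seq_len(i)
    rhoC[i, j] <- cIn[i - j + 1L]
    if (i > 1) acc <- acc + dt * (cIn[i - 1L] + cIn[i]) / 2
    pC[i] <- acc
  }
  total <- sA + pB + pC
  err <- max(abs(total - 1))
  if (err > tol)
    warning(sprintf(
      "grid too coarse: max |p_A+p_B+p_C-1| = %.3g > %.3g; reduce dt",
      err, tol))
  props <- cbind(ESC = sA, EPI = pB, NPC = pC)
  props <- pmin(pmax(props, 0), 1)
  props <- props / rowSums(props)
  list(time = tgrid, tau = tgrid, rho_A = sA, rho_B = rhoB, rho_C = rhoC,
       conservation_error = err,
       trajectory = MacrostateTrajectory(tgrid, props))
}
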