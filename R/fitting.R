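#' @importFrom stats optimize optim
NULL

#' Residual sum of squares between two trajectories
#'
#' Sum over times and the three macrostates of squared differences between
#' prediction and data. The time grids must match exactly.
#'
#' @param prediction,data [MacrostateTrajectory-class] objects on the same
#'   time grid.
#' @return nonnegative scalar.
#' @export
rssTrajectory <- function(prediction, data) {
  stopifnot(is(prediction, "MacrostateTrajectory"),
            is(data, "MacrostateTrajectory"))
  if (!isTRUE(all.equal(prediction@time, data@time)))
    stop("time grids do not match")
  sum((prediction@props - data@props)^2)
}

# ---------------------------------------------------------------------------
# continuous-model registry
# ---------------------------------------------------------------------------

# each entry: nPar, unpack (theta -> named param list), init (random theta),
# predict (params, times -> trajectory), smooth (TRUE: Levenberg-Marquardt,
# FALSE: Nelder-Mead on the RSS)
.contModels <- function(fixed = list()) list(
  first_order = list(
    nPar = 2, smooth = TRUE,
    unpack = function(th) list(q1 = exp(th[1]), q2 = exp(th[2])),
    init = function() log(1 / runif(2, 5, 100)),
    predict = function(p, times) solveFirstOrder(p$q1, p$q2, times)),
  paracrine_h1 = list(
    nPar = 3, smooth = TRUE,
    unpack = function(th) list(q1 = exp(th[1]), q2 = exp(th[2]),
                               K = exp(th[3])),
    init = function() c(log(1 / runif(2, 5, 100)), log(runif(1, 0.05, 0.9))),
    predict = function(p, times)
      solveParacrine(p$q1, p$q2, p$K, times = times, variant = "h1")),
  paracrine_free_h = list(
    nPar = 4, smooth = TRUE,
    unpack = function(th) list(q1 = exp(th[1]), q2 = exp(th[2]),
                               K = exp(th[3]), h = 1 + exp(th[4])),
    init = function() c(log(1 / runif(2, 5, 100)),
                        log(runif(1, 0.05, 0.9)), log(runif(1, 0.5, 4))),
    predict = function(p, times)
      solveParacrine(p$q1, p$q2, p$K, p$h, times, variant = "free_h")),
  paracrine_ultra = list(
    nPar = 3, smooth = FALSE,          # Heaviside switch: derivative-free
    unpack = function(th) list(q1 = exp(th[1]), q2 = exp(th[2]),
                               K = exp(th[3])),
    init = function() c(log(1 / runif(2, 5, 100)), log(runif(1, 0.05, 0.9))),
    predict = function(p, times)
      solveParacrine(p$q1, p$q2, p$K, times = times,
                     variant = "ultrasensitive")),
  conveyor_uniform = list(
    nPar = 4, smooth = FALSE,          # L = max(b, -a) + slack: kinked
    unpack = function(th) {
      a <- th[1]; b <- th[1] + exp(th[2])
      list(a = a, b = b, c_speed = exp(th[3]),
           L = max(b, -a) + exp(th[4]))
    },
    init = function() c(runif(1, -0.5, 0.5), log(runif(1, 0.2, 2)),
                        log(runif(1, 0.003, 0.05)), log(runif(1, 0.1, 2))),
    predict = function(p, times)
      solveConveyor(p$a, p$b, p$c_speed, init = "uniform", L = p$L,
                    times = times)),
  conveyor_gaussian = list(
    nPar = 5, smooth = TRUE,
    unpack = function(th) list(mu = th[1], sigma = exp(th[2]), a = th[3],
                               b = th[3] + exp(th[4]), c_speed = exp(th[5])),
    init = function() c(runif(1, -1, 0), log(runif(1, 0.1, 1)),
                        runif(1, 0, 1), log(runif(1, 0.2, 2)),
                        log(runif(1, 0.003, 0.05))),
    predict = function(p, times)
      solveConveyor(p$a, p$b, p$c_speed, init = "gaussian", mu = p$mu,
                    sigma = p$sigma, times = times)),
  reversible = list(
    nPar = 2, smooth = TRUE,           # nA, nB, N fixed via `fixed`
    unpack = function(th) list(qf = exp(th[1]), qb = exp(th[2])),
    init = function() c(log(1 / runif(1, 2, 20)), log(1 / runif(1, 50, 5000))),
    predict = function(p, times) {
      ch <- ChainParams(fixed$nA, fixed$nB,
                        N = if (is.null(fixed$N)) fixed$nB + 1 else fixed$N,
                        q = p$qf, qb = p$qb)
      solveReversible(ch, times)$trajectory
    })
)

#' Fit a continuous-parameter model by multistart least squares
#'
#' Minimizes the residual sum of squares between the model trajectory and
#' the data over the model's continuous parameters, from multiple random
#' starting points. Smooth models use the Levenberg-Marquardt algorithm
#' ([minpack.lm::nls.lm()]); models with discontinuous or kinked responses
#' (the ultrasensitive paracrine switch, the uniform conveyor boundaries)
#' use derivative-free Nelder-Mead. Positivity constraints are enforced by
#' log-parameterization.
#'
#' @param model one of `"first_order"`, `"paracrine_h1"`,
#'   `"paracrine_free_h"`, `"paracrine_ultra"`, `"conveyor_uniform"`,
#'   `"conveyor_gaussian"`, `"reversible"`.
#' @param data a [MacrostateTrajectory-class].
#' @param fixed named list of fixed structural parameters (`nA`, `nB`,
#'   optional `N` for the reversible chain).
#' @param restarts random restarts (default 20).
#' @param seed RNG seed for the restart draws.
#' @return A [FitResult-class]; `@path` logs every restart's objective.
#' @export
fitContinuous <- function(model, data, fixed = list(), restarts = 20,
                          seed = NULL) {
  stopifnot(is(data, "MacrostateTrajectory"))
  reg <- .contModels(fixed)
  if (!model %in% names(reg))
    stop("unknown continuous model: ", model)
  spec <- reg[[model]]
  times <- data@time
  residFn <- function(th) {
    p <- spec$unpack(th)
    pred <- tryCatch(spec$predict(p, times), error = function(e) NULL)
    if (is.null(pred)) return(rep(1e3, 3 * length(times)))
    as.vector(data@props - pred@props)
  }
  .withSeed(seed, {
    best <- NULL; log_obj <- numeric(restarts)
    for (r in seq_len(restarts)) {
      th0 <- spec$init()
      res <- tryCatch({
        if (spec$smooth) {
          fit <- minpack.lm::nls.lm(par = th0, fn = residFn,
                                    control = minpack.lm::nls.lm.control(
                                      maxiter = 500))
          list(par = fit$par, obj = sum(residFn(fit$par)^2))
        } else {
          fit <- optim(th0, function(th) sum(residFn(th)^2),
                       method = "Nelder-Mead",
                       control = list(maxit = 2000, reltol = 1e-12))
          list(par = fit$par, obj = fit$value)
        }
      }, error = function(e) NULL)
      log_obj[r] <- if (is.null(res)) NA_real_ else res$obj
      if (!is.null(res) && (is.null(best) || res$obj < best$obj)) best <- res
    }
    if (is.null(best))
      stop("no restart converged for model ", model)
    par <- spec$unpack(best$par)
    pred <- spec$predict(par, times)
    new("FitResult", model = model, par = par,
        objective = best$obj, lambda = 0, penalty = 0,
        residuals = as.vector(data@props - pred@props),
        trajectory = pred,
        path = data.frame(restart = seq_len(restarts), objective = log_obj),
        nPar = spec$nPar)
  })
}

# ---------------------------------------------------------------------------
# regularized chain fit
# ---------------------------------------------------------------------------

# profile table: best RSS and q for every admissible (nA, nB); lambda enters
# only through the separable penalty, so one table serves a whole lambda path
.chainRssTable <- function(data, nA_bounds = c(0, 30), nB_max = 60,
                           q_bounds = c(1 / 200, 2), weights = NULL) {
  times <- data@time
  yA <- data@props[, 1]; yB <- data@props[, 2]; yC <- data@props[, 3]
  if (is.null(weights)) weights <- matrix(1, length(times), 3)
  wA <- weights[, 1]; wB <- weights[, 2]; wC <- weights[, 3]
  rows <- list()
  for (nA in nA_bounds[1]:nA_bounds[2]) {
    for (nB in (nA + 1):nB_max) {
      # inlined chainMacrostates RSS: the inner loop is hot
      f <- function(q) {
        mu <- q * times
        FA <- ppois(nA, mu); FB <- ppois(nB, mu)
        sum(wA * (FA - yA)^2 + wB * (FB - FA - yB)^2 +
              wC * (1 - FB - yC)^2)
      }
      opt <- optimize(f, interval = q_bounds, tol = 1e-7)
      rows[[length(rows) + 1L]] <-
        c(nA = nA, nB = nB, q = opt$minimum, rss = opt$objective)
    }
  }
  as.data.frame(do.call(rbind, rows))
}

#' Fit the hidden microstate chain with complexity regularization
#'
#' Minimizes `||y - f||^2 + lambda (nA + nB)` jointly over the integer
#' block boundaries `nA < nB` and the continuous step rate `q`: an
#' exhaustive outer search over the integer grid with an inner 1-D least
#' squares over `q` per candidate. `N` is fixed at `nB + 1` (the terminal
#' NPC block is absorbing and collapsed; macrostate proportions do not
#' identify chain length beyond `nB`). Ties in the regularized objective
#' are broken toward fewer microstates.
#'
#' @param data a [MacrostateTrajectory-class] covering at least 3 times.
#' @param lambda regularization weight (default 1e-4).
#' @param nA_bounds integer bounds for `nA` (default 0..30).
#' @param nB_max largest `nB` considered (default 60).
#' @param q_bounds search interval for `q` in per-hour units.
#' @param weights optional times x 3 matrix of observation weights (e.g.
#'   inverse bootstrap variances); the default is the stated unweighted
#'   objective.
#' @param table precomputed profile table (internal reuse by the L-curve).
#' @return A [FitResult-class] with `par` = `nA`, `nB`, `N`, `q`.
#' @export
fitChain <- function(data, lambda = 1e-4, nA_bounds = c(0, 30), nB_max = 60,
                     q_bounds = c(1 / 200, 2), weights = NULL,
                     table = NULL) {
  stopifnot(is(data, "MacrostateTrajectory"))
  if (length(data@time) < 3) stop("need at least 3 timepoints")
  if (lambda < 0) stop("lambda must be >= 0")
  if (nA_bounds[2] + 1 > nB_max) stop("bounds exclude any nA < nB")
  if (is.null(table))
    table <- .chainRssTable(data, nA_bounds, nB_max, q_bounds, weights)
  obj <- table$rss + lambda * (table$nA + table$nB)
  ord <- order(obj, table$nA + table$nB, table$nA)
  best <- table[ord[1], ]
  chain <- ChainParams(best$nA, best$nB, q = best$q)
  pred <- chainMacrostates(chain, data@time)
  new("FitResult", model = "chain",
      par = list(nA = best$nA, nB = best$nB, N = best$nB + 1, q = best$q),
      objective = best$rss, lambda = lambda,
      penalty = best$nA + best$nB,
      residuals = as.vector(data@props - pred@props),
      trajectory = pred,
      path = table, nPar = 3)
}

#' Select the chain regularization weight by the L-curve
#'
#' Fits the regularized chain at every lambda on the grid, then picks the
#' lambda at the point of maximum curvature of the (log penalty, log
#' misfit) trade-off curve (Menger three-point curvature on the path
#' corners; ties broken toward larger lambda, i.e. parsimony). A flat path
#' with no corner falls back to the smallest lambda with a warning.
#'
#' @param data a [MacrostateTrajectory-class].
#' @param lambda_grid grid of >= 3 nonnegative weights.
#' @param ... passed to [fitChain()] (integer bounds etc.).
#' @return list with `lambda` (chosen), `fit` (the [FitResult-class] at the
#'   chosen weight) and `path` (data.frame lambda, nA, nB, q, rss, penalty).
#' @export
selectLambdaLcurve <- function(data,
                               lambda_grid = 10^seq(-6, -1, length.out = 20),
                               ...) {
  if (length(lambda_grid) < 3) stop("lambda_grid needs >= 3 values")
  lambda_grid <- sort(lambda_grid)
  table <- .chainRssTable(data, ...)
  pick <- function(lam) {
    obj <- table$rss + lam * (table$nA + table$nB)
    ord <- order(obj, table$nA + table$nB, table$nA)
    table[ord[1], ]
  }
  path <- do.call(rbind, lapply(lambda_grid, pick))
  path <- data.frame(lambda = lambda_grid, nA = path$nA, nB = path$nB,
                     q = path$q, rss = path$rss,
                     penalty = path$nA + path$nB)
  # the trade-off curve is the penalty-vs-misfit frontier of the profile
  # table: per complexity nA + nB, the best achievable RSS (monotonized so
  # extra complexity never hurts). The lambda path alone can miss the flat
  # branch of the L when the global minimizer is already the corner model.
  pen <- sort(unique(table$nA + table$nB))
  rfr <- vapply(pen, function(p)
    min(table$rss[table$nA + table$nB == p]), 0)
  rfr <- rev(cummin(rev(rfr)))
  x <- log(pen)
  y <- log(pmax(rfr, 1e-300))
  n <- length(pen)
  curv <- rep(0, n)
  if (n >= 3) for (i in 2:(n - 1)) {
    p1 <- c(x[i - 1], y[i - 1]); p2 <- c(x[i], y[i]); p3 <- c(x[i + 1], y[i + 1])
    a <- sqrt(sum((p2 - p1)^2)); b <- sqrt(sum((p3 - p2)^2))
    cc <- sqrt(sum((p3 - p1)^2))
    if (a * b * cc < 1e-12) next       # coincident corners: no curvature
    area2 <- abs((p2[1] - p1[1]) * (p3[2] - p1[2]) -
                 (p3[1] - p1[1]) * (p2[2] - p1[2]))
    # only convex corners of the L count (misfit levelling off, not
    # accelerating)
    if ((p2[2] - p1[2]) / (p2[1] - p1[1]) <
        (p3[2] - p2[2]) / (p3[1] - p2[1]))
      curv[i] <- 2 * area2 / (a * b * cc)
  }
  if (all(curv == 0)) {
    warning("flat L-curve: no corner found; using smallest lambda")
    lam <- lambda_grid[1]
  } else {
    corner_pen <- pen[max(which(curv == max(curv)))]
    # largest grid lambda that still selects at least the corner complexity
    # (ties broken toward larger lambda, i.e. parsimony)
    ok <- which(path$penalty >= corner_pen)
    lam <- if (length(ok)) lambda_grid[max(ok)] else lambda_grid[1]
  }
  list(lambda = lam, fit = fitChain(data, lambda = lam, table = table, ...),
       path = path)
}

#' Fit and compare competing transition models
#'
#' Fits each requested model with its designated routine (the regularized
#' integer search for `"chain"`, multistart least squares otherwise) and
#' tabulates the results ordered by residual sum of squares, ties broken by
#' parameter count.
#'
#' @param data a [MacrostateTrajectory-class].
#' @param models character vector of model names (`"chain"` plus any
#'   continuous model known to [fitContinuous()]).
#' @param fixed passed to [fitContinuous()] (the reversible chain's blocks).
#' @param lambda passed to [fitChain()].
#' @param restarts,seed passed to [fitContinuous()].
#' @return list with `fits` (named list of [FitResult-class]) and `table`
#'   (data.frame model, rss, n_par, ordered by fit quality).
#' @export
compareModels <- function(data, models = c("first_order", "paracrine_h1",
                                           "chain"),
                          fixed = list(), lambda = 1e-4, restarts = 20,
                          seed = NULL) {
  if (!length(models)) stop("need at least one model")
  fits <- list()
  for (i in seq_along(models)) {
    m <- models[i]
    fits[[m]] <- if (m == "chain") fitChain(data, lambda = lambda)
    else fitContinuous(m, data, fixed = fixed, restarts = restarts,
                       seed = if (is.null(seed)) NULL else seed + i)
  }
  tab <- data.frame(model = names(fits),
                    rss = vapply(fits, fitObjective, 0),
                    n_par = vapply(fits, function(f) f@nPar, 0))
  tab <- tab[order(tab$rss, tab$n_par), ]
  rownames(tab) <- NULL
  list(fits = fits, table = tab)
}
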