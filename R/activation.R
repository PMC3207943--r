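# Refractory readiness profiles g and the numerical solution of the
# functional equation defining the matched activation function f.
#
# For the discrete-time relative refractory mechanism the single-neuron chain
# on zeta in {0, ..., tau} (re-fire from any state with probability
# g(zeta) f(u), otherwise decay by one) has stationary P(v = 1) = sigma(u)
# exactly when f(u) solves
#
#     L(f) = f * sum_{z=1}^{tau} prod_{i=1}^{z} (1 - g(i) f)^(-1)  =  e^u .
#
# L is continuous and strictly increasing on (0, 1/gamma) with
# gamma = max_z g(z), with limits 0 and +infinity, so a unique root exists
# for every real u and bisection is globally safe.  For the absolute profile
# (g(1) = 1, g(z) = 0 otherwise) the equation reduces to
# f tau / (1 - f) = e^u, i.e. f(u) = sigma(u - log tau).

#' Construct a refractory readiness profile
#'
#' The readiness g(zeta) of a neuron to re-fire while its refractory variable
#' is still counting down.  `kind = "absolute"` gives the profile of the
#' absolute refractory mechanism: zero readiness in every refractory state
#' except the last (zeta = 1), where the neuron behaves as if at rest.  The
#' named relative profiles are power-law recoveries
#' \eqn{g(\zeta) = ((\tau-\zeta)/(\tau-1))^p}: "early" (p = 0.5, readiness
#' returns quickly), "moderate" (p = 2), "late" (p = 8, close to an absolute
#' mechanism).  `kind = "table"` accepts an arbitrary user table (monotonic
#' or not) via `values`.
#'
#' @param kind one of "absolute", "early", "moderate", "late", "table".
#' @param tau refractory length in steps (ignored for "table").
#' @param values numeric vector g(1), ..., g(tau) for `kind = "table"`.
#' @return A [RefractoryProfile-class] object.
#' @examples
#' makeProfile("absolute", tau = 3)   # g = (1, 0, 0) on zeta = 1, 2, 3
#' makeProfile("moderate", tau = 20)
#' @export
makeProfile <- function(kind = c("absolute", "early", "moderate", "late",
                                 "table"),
                        tau = 20L, values = NULL) {
  kind <- match.arg(kind)
  if (kind == "table") {
    if (is.null(values)) stop("kind = 'table' requires values")
    return(new("RefractoryProfile", values = as.numeric(values),
               kind = "table"))
  }
  tau <- as.integer(tau)
  stopifnot(tau >= 1L)
  g <- numeric(tau)                       # indexed by zeta = 1..tau
  if (kind == "absolute") {
    g[1] <- 1
  } else {
    if (tau < 2L) stop("relative profiles need tau >= 2")
    p <- switch(kind, early = 0.5, moderate = 2, late = 8)
    z <- seq_len(tau)
    g <- ((tau - z) / (tau - 1))^p
  }
  new("RefractoryProfile", values = g, kind = kind)
}

# L(f) of the defining equation, vectorised over f (one value per u being
# solved).  Computed via cumulative products for numerical transparency.
.activationLhs <- function(f, g) {
  tau <- length(g)
  acc <- rep(1, length(f))
  s <- rep(0, length(f))
  for (z in seq_len(tau)) {
    acc <- acc / (1 - g[z] * f)
    s <- s + acc
  }
  f * s
}

#' Residual of the activation-function equation
#'
#' Evaluates \eqn{L(f) - e^u} for given f and u under profile g; the solved
#' activation function drives this to zero at every grid node.
#'
#' @param g a [RefractoryProfile-class] object.
#' @param f activation values (same length as u).
#' @param u membrane potentials.
#' @return numeric residuals.
#' @export
activationResidual <- function(g, f, u) {
  .activationLhs(f, g@values) - exp(u)
}

#' Solve the activation function for a readiness profile
#'
#' For each grid node u, finds the unique f(u) in (0, 1/max(g)) satisfying
#' the local-correctness equation (see [activationResidual()]), by bisection
#' (the left-hand side is strictly increasing in f, so bracketing is
#' globally safe).  Out-of-range lookups are clipped to the end nodes.
#'
#' @param g a [RefractoryProfile-class] object.
#' @param uGrid sorted grid of membrane potentials; the default [-10, 10]
#'   with step 0.01 covers the logistic function to within 5e-5 at the ends.
#' @param tol absolute tolerance of the root in f.
#' @return An [ActivationFunction-class] object.
#' @examples
#' af <- solveActivation(makeProfile("absolute", tau = 4),
#'                       uGrid = seq(-2, 2, 0.5))
#' max(abs(af@fValues - sigmoid(af@uGrid - log(4))))  # ~1e-10
#' @export
solveActivation <- function(g, uGrid = seq(-10, 10, by = 0.01), tol = 1e-10) {
  gv <- g@values
  gamma <- max(gv)
  eu <- exp(uGrid)
  eps <- 1e-12
  lo <- rep(eps, length(uGrid))
  # firing probabilities g(0) f = f must stay below 1, so the search is
  # capped at min(1, 1/gamma); profiles that never recover full readiness
  # (max g < 1) cannot represent large membrane potentials
  hi <- rep((1 - eps) / max(gamma, 1), length(uGrid))
  if (any(.activationLhs(hi, gv) < eu))
    stop("no activation value below 1 solves the equation at the largest ",
         "grid potentials; the profile must recover full readiness ",
         "(max g = 1)")
  # vectorised bisection to machine precision (64 halvings)
  for (i in seq_len(64L)) {
    mid <- (lo + hi) / 2
    high <- .activationLhs(mid, gv) > eu
    hi[high] <- mid[high]
    lo[!high] <- mid[!high]
  }
  f <- (lo + hi) / 2
  if (any(f <= 0) || any(f >= 1))
    stop("root not bracketed in (0, 1); malformed readiness profile")
  new("ActivationFunction", uGrid = as.numeric(uGrid), fValues = f,
      profile = g, tol = tol)
}

#' Evaluate a tabulated activation function
#'
#' Piecewise-constant lookup: each u is mapped to the nearest grid node;
#' values outside the grid are clipped to the end nodes with a warning.
#'
#' @param af an [ActivationFunction-class] object.
#' @param u membrane potentials.
#' @return f(u) values.
#' @export
evalActivation <- function(af, u) {
  grid <- af@uGrid
  if (any(u < grid[1] - 1e-9) || any(u > grid[length(grid)] + 1e-9))
    warning("membrane potential outside activation grid; clipping to ends")
  step <- grid[2] - grid[1]
  idx <- round((u - grid[1]) / step) + 1
  idx <- pmin(pmax(idx, 1), length(grid))
  af@fValues[idx]
}

#' Solve the continuous-time activation function
#'
#' In continuous time the refractory variable decays linearly from tau to 0
#' after a spike and the neuron re-fires with rate density g(zeta) f(u)
#' (rate f(u) at rest, g(0) = 1 by convention).  Requiring the stationary
#' active-time fraction of this renewal process to equal sigma(u) for every
#' u yields the integral equation
#' \deqn{f \int_0^{\tau} \exp\left(f \int_0^{x} g(\zeta)\,d\zeta\right) dx
#'   = e^u,}
#' whose left-hand side is strictly increasing in f from 0 to infinity, so a
#' unique rate exists for every u.  Inner integrals use adaptive quadrature;
#' the root is found by bracketed search.  For \eqn{g \equiv 0} on
#' \eqn{(0,\tau]} (the absolute mechanism) the solution is the closed form
#' \eqn{f(u) = e^u/\tau}; for \eqn{g \equiv 1} (no refractory modulation) it
#' is \eqn{f(u) = \log(1 + e^u)/\tau}.
#'
#' @param g function of zeta on [0, tau], continuous, nonnegative, with
#'   g(tau) = 0.
#' @param tau refractory duration (ms).
#' @param tol relative tolerance of the solved rate.
#' @return a vectorised function f(u) returning rates in 1/ms.
#' @export
solveActivationContinuous <- function(g, tau, tol = 1e-8) {
  if (abs(g(tau)) > 1e-8) stop("g(tau) must be 0")
  # cumulative integral G(x) = int_0^x g, by adaptive quadrature on a cache
  gridX <- seq(0, tau, length.out = 201L)
  Gvals <- numeric(length(gridX))
  for (i in seq_along(gridX)[-1]) {
    q <- stats::integrate(function(z) vapply(z, g, numeric(1)),
                          gridX[i - 1L], gridX[i],
                          rel.tol = tol / 10, abs.tol = tol / 10)
    if (q$message != "OK") stop("quadrature failed: ", q$message)
    Gvals[i] <- Gvals[i - 1L] + q$value
  }
  Gfun <- stats::approxfun(gridX, Gvals, rule = 2)
  # composite Simpson on a fine fixed grid: the integrand exp(f G(x)) spans
  # many orders of magnitude, which defeats adaptive quadrature's error
  # heuristics, while the function itself is perfectly smooth
  nq <- 2001L
  xq <- seq(0, tau, length.out = nq)
  wq <- c(1, rep(c(4, 2), (nq - 3) / 2), 4, 1) * (xq[2] - xq[1]) / 3
  Gq <- Gfun(xq)
  lhs <- function(f) f * sum(wq * exp(f * Gq))
  solveOne <- function(u) {
    target <- exp(u)
    hi <- 1 / tau
    while (lhs(hi) < target) hi <- hi * 2
    stats::uniroot(function(f) lhs(f) - target, c(0, hi),
                   tol = tol * max(hi, 1e-12))$root
  }
  function(u) vapply(u, solveOne, numeric(1))
}
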