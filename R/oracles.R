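# Ground-truth machinery: Gibbs reference sampler, exhaustive sweep
# transition matrices for tiny networks, stationary-distribution and
# reversibility diagnostics.

#' Gibbs reference sampler on the binary target
#'
#' Systematic-scan Gibbs sampling of v using the exact conditional
#' probabilities \eqn{\sigma(u_k)}; the ground-truth reference against which
#' the spiking samplers are compared.
#'
#' @param params a [BoltzmannParams-class] object.
#' @param nScans recorded scans.
#' @param burnIn discarded initial scans.
#' @param seed optional integer seed.
#' @param thin snapshot spacing in scans.
#' @param recordStates,countStates see [runChain()].
#' @return list with elements `states` (matrix or NULL) and `counts`
#'   (numeric vector over state codes or NULL).
#' @export
gibbsChain <- function(params, nScans, burnIn = 1000L, seed = NULL,
                       thin = 1L, recordStates = TRUE, countStates = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_gibbs(params@W, params@b, as.integer(nScans),
                   as.integer(burnIn), as.integer(thin),
                   recordStates, countStates)
  list(states = res$states, counts = res$counts)
}

# per-neuron operator matrix over the (tau+1)^K refractory configurations,
# as a sparse row-stochastic matrix.  `fire[z, u]` gives the firing
# probability from zeta = z (0-based) under membrane potential u.
.neuronOperator <- function(k, params, tau, mechanism, g = NULL, f = NULL) {
  K <- nNeurons(params)
  base <- tau + 1L
  zetas <- zetaStateMatrix(K, tau)
  nS <- nrow(zetas)
  v <- (zetas > 0) * 1
  u <- as.numeric(v %*% params@W[, k]) + params@b[k] -
    params@W[k, k] * v[, k]                       # diagonal is zero anyway
  z <- zetas[, k]
  if (mechanism == "absolute") {
    pFire <- ifelse(z <= 1, sigmoid(u - log(tau)), 0)
    decayTo <- ifelse(z > 1, z - 1, 0)
  } else {
    gz <- profileValues(g)[z + 1]
    pFire <- gz * evalActivation(f, u)
    decayTo <- pmax(z - 1, 0)
  }
  off <- base^(k - 1L)
  from <- seq_len(nS)
  toFire <- from + (tau - z) * off
  toDecay <- from + (decayTo - z) * off
  i <- c(from, from)
  j <- c(toFire, toDecay)
  x <- c(pFire, 1 - pFire)
  keep <- x > 0
  Matrix::sparseMatrix(i = i[keep], j = j[keep], x = x[keep],
                       dims = c(nS, nS))
}

#' Exact one-sweep transition matrix of a small network
#'
#' Assembles the sweep operator as the ordered product of the K per-neuron
#' operator matrices (neuron 1 applied first), each built directly from the
#' transition definitions -- no sampling involved.
#'
#' @param params a [BoltzmannParams-class] object.
#' @param tau integer refractory length.
#' @param mechanism "absolute" or "relative".
#' @param g,f profile and activation function for the relative mechanism.
#' @param maxStates guard on (tau+1)^K.
#' @return A [TransitionMatrixOracle-class] object.
#' @export
buildTransitionMatrix <- function(params, tau, mechanism = "absolute",
                                  g = NULL, f = NULL, maxStates = 1e5) {
  K <- nNeurons(params)
  tau <- as.integer(tau)
  if ((tau + 1)^K > maxStates) stop("state space too large")
  if (mechanism == "relative") {
    if (is.null(g) || is.null(f))
      stop("relative mechanism requires g and f")
    if (profileTau(g) != tau) stop("profile tau mismatch")
  }
  Tm <- .neuronOperator(1L, params, tau, mechanism, g, f)
  for (k in seq_len(K)[-1])
    Tm <- Tm %*% .neuronOperator(k, params, tau, mechanism, g, f)
  new("TransitionMatrixOracle", matrix = Tm, K = as.integer(K), tau = tau,
      mechanism = mechanism)
}

#' Invariance and reversibility diagnostics
#'
#' Checks how a candidate distribution relates to an exhaustive sweep
#' operator: the invariance residual \eqn{\max_x |(pT)_x - p_x|}, the
#' stationary distribution (left eigenvector of eigenvalue 1), the
#' multiplicity of eigenvalue 1 (counting \eqn{|\lambda - 1| < 10^{-9}};
#' multiplicity one certifies irreducibility + aperiodicity on the reachable
#' chain), and the maximum detailed-balance residual
#' \eqn{\max_{x,x'} |p_x T_{xx'} - p_{x'} T_{x'x}|} (strictly positive for
#' these irreversible chains).
#'
#' @param oracle a [TransitionMatrixOracle-class] object.
#' @param pJoint a [JointAuxDistribution-class] or numeric probability
#'   vector over the oracle's states.
#' @param denseLimit maximum number of states for dense eigendecomposition;
#'   above it the stationary distribution is found by power iteration
#'   (tolerance 1e-13) and the multiplicity is reported as NA.
#' @return list with `invariance_residual`, `stationary`, `eig1_multiplicity`,
#'   `detailed_balance_residual`, `row_stochastic_residual`.
#' @export
checkInvariance <- function(oracle, pJoint, denseLimit = 4000L) {
  Tm <- oracle@matrix
  p <- if (is(pJoint, "JointAuxDistribution")) pJoint@probs
       else as.numeric(pJoint)
  if (length(p) != nrow(Tm)) stop("dimension mismatch")
  rowRes <- max(abs(Matrix::rowSums(Tm) - 1))
  invRes <- max(abs(as.numeric(p %*% Tm) - p))

  nS <- nrow(Tm)
  if (nS <= denseLimit) {
    ev <- eigen(t(as.matrix(Tm)))
    mult <- sum(abs(ev$values - 1) < 1e-9)
    i1 <- which.min(abs(ev$values - 1))
    stat <- Re(ev$vectors[, i1])
    stat <- stat / sum(stat)
  } else {
    stat <- rep(1 / nS, nS)
    for (it in seq_len(1e6)) {
      nxt <- as.numeric(stat %*% Tm)
      if (max(abs(nxt - stat)) < 1e-13) { stat <- nxt; break }
      stat <- nxt
    }
    mult <- NA_integer_
  }

  Td <- as.matrix(Tm)
  flow <- p * Td                       # flow[x, y] = p_x T_{x,y}
  dbRes <- max(abs(flow - t(flow)))
  list(invariance_residual = invRes, stationary = stat,
       eig1_multiplicity = mult, detailed_balance_residual = dbRes,
       row_stochastic_residual = rowRes)
}

#' Marginalise a joint refractory-state distribution onto binary states
#'
#' @param probs numeric vector over the (tau+1)^K refractory configurations.
#' @param K,tau dimensions of the enumeration.
#' @return numeric vector of length 2^K over binary state codes.
#' @export
marginalizeZeta <- function(probs, K, tau) {
  zetas <- zetaStateMatrix(K, tau)
  codes <- stateCode((zetas > 0) * 1L)
  as.numeric(rowsum(probs, codes)[as.character(0:(2^K - 1)), 1])
}
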