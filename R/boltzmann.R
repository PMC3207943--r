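# model core: exact enumeration, membrane potentials, augmented joint
# distribution, random ensembles.

#' Enumerate all binary states of K variables
#'
#' Row i (1-based) is the binary vector with integer code i-1; neuron 1 is
#' the least-significant bit.
#'
#' @param K number of binary variables (K <= 20).
#' @return 2^K x K integer matrix of 0/1 values.
#' @export
stateMatrix <- function(K) {
  stopifnot(K >= 1, K <= 20)
  codes <- 0:(2^K - 1)
  m <- matrix(0L, length(codes), K)
  for (k in seq_len(K)) m[, k] <- bitwAnd(bitwShiftR(codes, k - 1L), 1L)
  m
}

#' Integer codes of binary state rows
#'
#' @param v matrix of 0/1 values (rows = states) or a single 0/1 vector.
#' @return integer codes, neuron 1 = least-significant bit.
#' @export
stateCode <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  as.integer(v %*% 2^(seq_len(ncol(v)) - 1))
}

#' Exact Boltzmann distribution by enumeration
#'
#' Computes the normalised probability table
#' \eqn{p(v) = Z^{-1}\exp(\sum_k b_k v_k + \frac{1}{2}\sum_{k,j} W_{kj} v_k v_j)}
#' over all 2^K binary states.  The one-half factor goes with the full
#' symmetric double sum, so each pair contributes \eqn{W_{kj} v_k v_j} once.
#'
#' @param params a [BoltzmannParams-class] object with K <= 20.
#' @return An [ExactDistribution-class] object.
#' @examples
#' d <- exactDistribution(boltzmannParams(matrix(0, 2, 2), c(0, 0)))
#' stateProbs(d)  # all four states 0.25
#' @export
exactDistribution <- function(params) {
  K <- nNeurons(params)
  if (K > 20) stop("exact enumeration is limited to K <= 20")
  V <- stateMatrix(K)
  lp <- as.numeric(V %*% params@b + 0.5 * rowSums((V %*% params@W) * V))
  m <- max(lp)
  w <- exp(lp - m)
  Z <- sum(w)
  new("ExactDistribution", probs = w / Z, logZ = m + log(Z), K = as.integer(K))
}

#' Membrane potential of one neuron
#'
#' The neural computability condition requires the membrane potential of
#' neuron k to equal the log-odds of its variable being active given the
#' others; for a Boltzmann distribution this is the linear sum
#' \eqn{u_k = b_k + \sum_{j \ne k} W_{kj} v_j}.
#'
#' @param params a [BoltzmannParams-class] object.
#' @param state a [NetworkState-class] object (v derived as zeta > 0) or a
#'   0/1 vector.
#' @param k neuron index (1-based).
#' @return the membrane potential u_k.
#' @export
membranePotential <- function(params, state, k) {
  K <- nNeurons(params)
  if (k < 1 || k > K) stop("neuron index out of range")
  v <- if (is(state, "NetworkState")) binaryState(state) else as.numeric(state)
  params@b[k] + sum(params@W[k, ] * v)   # W[k,k] = 0, so v_k drops out
}

#' Membrane potentials for a set of state snapshots
#'
#' @param params a [BoltzmannParams-class] object.
#' @param states matrix of 0/1 state snapshots (rows = time points).
#' @return matrix of u values, same shape as `states`.
#' @export
membranePotentialTrace <- function(params, states) {
  sweep2 <- states %*% params@W
  sweep2 + matrix(params@b, nrow(states), ncol(states), byrow = TRUE)
}

#' Augmented joint distribution over (v, zeta)
#'
#' The discrete-time sampler targets the joint distribution in which the
#' binary marginal is the Boltzmann distribution and, given \eqn{v_k = 1},
#' the refractory variable \eqn{\zeta_k} is uniform on \eqn{\{1,\dots,\tau\}}
#' (with \eqn{\zeta_k = 0} exactly when \eqn{v_k = 0}).
#'
#' @param params a [BoltzmannParams-class] object.
#' @param tau integer refractory length.
#' @param maxStates guard on the joint state-space size (tau+1)^K.
#' @return A [JointAuxDistribution-class] object; probabilities are indexed
#'   by the code \eqn{\sum_k \zeta_k (\tau+1)^{k-1}}.
#' @export
jointAuxDistribution <- function(params, tau, maxStates = 1e6) {
  K <- nNeurons(params)
  tau <- as.integer(tau)
  nS <- (tau + 1)^K
  if (nS > maxStates) stop("joint state space too large to enumerate")
  p <- exactDistribution(params)
  zetas <- zetaStateMatrix(K, tau)
  v <- (zetas > 0) * 1L
  codes <- stateCode(v)
  nActive <- rowSums(v)
  probs <- p@probs[codes + 1L] * (1 / tau)^nActive
  new("JointAuxDistribution", probs = probs, K = as.integer(K), tau = tau)
}

#' Enumerate all refractory configurations
#'
#' @param K number of neurons.
#' @param tau refractory length.
#' @return (tau+1)^K x K integer matrix; row i is the configuration with
#'   code i-1 (neuron 1 varies fastest).
#' @export
zetaStateMatrix <- function(K, tau) {
  base <- tau + 1L
  codes <- 0:(base^K - 1)
  m <- matrix(0L, length(codes), K)
  rest <- codes
  for (k in seq_len(K)) {
    m[, k] <- rest %% base
    rest <- rest %/% base
  }
  m
}

#' Random Boltzmann distribution ensemble member
#'
#' Off-diagonal weights are drawn i.i.d. from a zero-mean normal with
#' standard deviation `sigmaW` (symmetrised, zero diagonal); biases from
#' Normal(`muB`, `sigmaB`^2).  The defaults for the bias prior
#' (mean -1.5, sd 0.5) give the sparse, low-activity regimes typical of the
#' random-ensemble experiments.
#'
#' @param K number of variables.
#' @param sigmaW weight standard deviation (>= 0).
#' @param muB bias mean.
#' @param sigmaB bias standard deviation (>= 0).
#' @param seed optional integer seed for reproducibility.
#' @return A [BoltzmannParams-class] object.
#' @export
randomBoltzmann <- function(K, sigmaW, muB = -1.5, sigmaB = 0.5, seed = NULL) {
  stopifnot(sigmaW >= 0, sigmaB >= 0)
  if (!is.null(seed)) set.seed(seed)
  W <- matrix(0, K, K)
  nOff <- K * (K - 1) / 2
  if (nOff > 0) W[upper.tri(W)] <- rnorm(nOff, 0, sigmaW)
  W <- W + t(W)
  b <- rnorm(K, muB, sigmaB)
  boltzmannParams(W, b)
}

#' Fully factorised approximation
#'
#' The product of the K single-variable marginals of the input distribution:
#' the baseline that keeps the correct marginals but drops all statistical
#' dependencies.
#'
#' @param exact an [ExactDistribution-class] object.
#' @return An [ExactDistribution-class] object (the product distribution).
#' @export
factorizedApprox <- function(exact) {
  K <- exact@K
  V <- stateMatrix(K)
  marg <- as.numeric(crossprod(V, exact@probs))      # P(v_k = 1)
  lp <- V %*% log(marg) + (1 - V) %*% log1p(-marg)
  probs <- exp(as.numeric(lp))
  probs <- probs / sum(probs)                        # guard against roundoff
  new("ExactDistribution", probs = probs, logZ = 0, K = K)
}

#' Single-variable marginals of an exact distribution
#'
#' @param exact an [ExactDistribution-class] object.
#' @return numeric vector of P(v_k = 1), k = 1..K.
#' @export
stateMarginals <- function(exact) {
  as.numeric(crossprod(stateMatrix(exact@K), exact@probs))
}

#' Number of states carrying a given probability mass
#'
#' The minimal number m of highest-probability states whose cumulative
#' probability reaches at least `fraction`.  Ties are broken by the fixed
#' state ordering (lower state code first), which cannot change m.
#'
#' @param exact an [ExactDistribution-class] object.
#' @param fraction target cumulative probability in (0, 1].
#' @return integer count of states.
#' @export
massConcentrationCount <- function(exact, fraction = 0.9) {
  stopifnot(fraction > 0, fraction <= 1)
  sorted <- sort(exact@probs, decreasing = TRUE, method = "radix")
  as.integer(which(cumsum(sorted) >= fraction - 1e-15)[1])
}

#' Logistic function
#'
#' @param x numeric vector.
#' @return 1 / (1 + exp(-x)).
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))
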