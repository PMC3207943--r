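# Small shared fixtures, built in code.

# a fixed 2-neuron system with moderate coupling
fixtureParams2 <- function() {
  boltzmannParams(matrix(c(0, 0.8, 0.8, 0), 2), c(-0.5, 0.3))
}

# a fixed 3-neuron system
fixtureParams3 <- function() {
  W <- matrix(0, 3, 3)
  W[upper.tri(W)] <- c(0.6, -0.4, 1.1)
  W <- W + t(W)
  boltzmannParams(W, c(-1, 0.2, 0.5))
}

# brute-force Boltzmann probabilities, computed term by term, independently
# of stateMatrix/exactDistribution internals
bruteForceProbs <- function(W, b) {
  K <- length(b)
  states <- expand.grid(rep(list(0:1), K))
  e <- apply(states, 1, function(v) {
    s <- sum(b * v)
    for (k in seq_len(K)) for (j in seq_len(K))
      s <- s + 0.5 * W[k, j] * v[k] * v[j]
    s
  })
  # expand.grid varies the first variable fastest, matching the
  # least-significant-bit state coding
  exp(e) / sum(exp(e))
}

# dense per-neuron transition operator for the absolute mechanism, built by
# an independent loop over all states (oracle for buildTransitionMatrix)
denseNeuronOperatorAbs <- function(k, params, tau) {
  K <- nNeurons(params)
  zetas <- zetaStateMatrix(K, tau)
  nS <- nrow(zetas)
  M <- matrix(0, nS, nS)
  for (s in seq_len(nS)) {
    z <- zetas[s, ]
    v <- as.numeric(z > 0)
    u <- params@b[k] + sum(params@W[k, ] * v)
    znew <- z
    if (z[k] > 1) {
      znew[k] <- z[k] - 1
      M[s, 1 + sum(znew * (tau + 1)^(seq_len(K) - 1))] <- 1
    } else {
      p <- 1 / (1 + exp(-(u - log(tau))))
      znew[k] <- tau
      M[s, 1 + sum(znew * (tau + 1)^(seq_len(K) - 1))] <- p
      znew[k] <- 0
      M[s, 1 + sum(znew * (tau + 1)^(seq_len(K) - 1))] <-
        M[s, 1 + sum(znew * (tau + 1)^(seq_len(K) - 1))] + 1 - p
    }
  }
  M
}
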