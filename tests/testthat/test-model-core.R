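test_that("exact distribution matches closed forms and the energy oracle", {
  # zero parameters: uniform over the four states
  d <- exactDistribution(boltzmannParams(matrix(0, 2, 2), c(0, 0)))
  expect_equal(stateProbs(d), rep(0.25, 4))

  # single variable: logistic closed form
  for (beta in c(-2, 0, 1.3)) {
    d1 <- exactDistribution(boltzmannParams(matrix(0, 1, 1), beta))
    expect_equal(stateProbs(d1)[2], sigmoid(beta), tolerance = 1e-12)
  }

  # random K = 3 system: term-by-term brute-force oracle, and probability
  # ratios equal exponentiated energy differences
  p <- fixtureParams3()
  d3 <- exactDistribution(p)
  expect_equal(stateProbs(d3), bruteForceProbs(weightMatrix(p), biases(p)),
               tolerance = 1e-12)
  expect_equal(sum(stateProbs(d3)), 1, tolerance = 1e-12)
  expect_true(all(stateProbs(d3) > 0))
})

test_that("parameter validation rejects malformed weight matrices", {
  W <- matrix(c(0, 1, 2, 0), 2)                 # asymmetric
  expect_error(boltzmannParams(W, c(0, 0)), "symmetric")
  W2 <- matrix(c(1, 0.5, 0.5, 0), 2)            # nonzero diagonal
  expect_error(boltzmannParams(W2, c(0, 0)), "diagonal")
  expect_error(exactDistribution(randomBoltzmann(21, 0.1, seed = 1)),
               "K <= 20")
})

test_that("membrane potential satisfies the neural computability condition", {
  p <- fixtureParams3()
  d <- exactDistribution(p)
  # empty network input: u_k = b_k
  expect_equal(membranePotential(p, networkState(c(0, 0, 0), 4), 1),
               biases(p)[1])
  # single active partner adds one weight
  expect_equal(membranePotential(p, networkState(c(0, 3, 0), 4), 1),
               biases(p)[1] + weightMatrix(p)[1, 2])
  # u_k equals the conditional log-odds from exact enumeration, for every
  # neuron in every state of enumerable systems
  set.seed(5)
  for (K in 2:5) {
    pk <- randomBoltzmann(K, 0.7, seed = K)
    dk <- exactDistribution(pk)
    V <- stateMatrix(K)
    for (code in 0:(2^K - 1)) {
      v <- V[code + 1, ]
      for (k in seq_len(K)) {
        u <- membranePotential(pk, networkState(v * 3, 3), k)
        c1 <- stateCode(replace(v, k, 1L)); c0 <- stateCode(replace(v, k, 0L))
        logOdds <- log(stateProbs(dk)[c1 + 1] / stateProbs(dk)[c0 + 1])
        expect_lt(abs(u - logOdds), 1e-10)
      }
    }
  }
  expect_error(membranePotential(p, networkState(c(0, 0, 0), 4), 4),
               "out of range")
})

test_that("joint auxiliary distribution has the right product structure", {
  # K = 1, tau = 4, b = 0: p(zeta = 0) = 1/2, p(zeta = i) = 1/8
  j1 <- jointAuxDistribution(boltzmannParams(matrix(0, 1, 1), 0), 4)
  expect_equal(j1@probs, c(0.5, rep(0.125, 4)))

  # marginalising over zeta recovers the exact distribution
  p <- fixtureParams2()
  j <- jointAuxDistribution(p, 3)
  expect_equal(marginalizeZeta(j@probs, 2, 3),
               stateProbs(exactDistribution(p)), tolerance = 1e-14)

  # K = 2, tau = 2: all 9 joint probabilities match direct product-form
  # evaluation
  j2 <- jointAuxDistribution(p, 2)
  ex <- stateProbs(exactDistribution(p))
  zetas <- zetaStateMatrix(2, 2)
  for (s in seq_len(nrow(zetas))) {
    z <- zetas[s, ]
    v <- as.numeric(z > 0)
    expected <- ex[stateCode(v) + 1] * prod(ifelse(v == 1, 1 / 2, 1))
    expect_equal(j2@probs[s], expected, tolerance = 1e-14)
  }
  expect_equal(sum(j2@probs), 1, tolerance = 1e-12)
})

test_that("random ensembles are reproducible and correctly scaled", {
  expect_equal(weightMatrix(randomBoltzmann(5, 0, seed = 1)),
               matrix(0, 5, 5))
  a <- randomBoltzmann(8, 1.4, seed = 99)
  b <- randomBoltzmann(8, 1.4, seed = 99)
  expect_identical(weightMatrix(a), weightMatrix(b))
  expect_identical(biases(a), biases(b))

  # empirical sd of off-diagonals across 100 draws within 3 SE of sigma_w
  set.seed(7)
  offs <- unlist(lapply(1:100, function(i) {
    W <- weightMatrix(randomBoltzmann(10, 3.0))
    W[upper.tri(W)]
  }))
  se <- 3.0 / sqrt(2 * (length(offs) - 1))
  expect_lt(abs(sd(offs) - 3.0), 3 * se)
})

test_that("factorized approximation keeps marginals and drops dependence", {
  # independent input is a fixed point
  d0 <- exactDistribution(boltzmannParams(matrix(0, 3, 3), c(-1, 0, 2)))
  expect_equal(stateProbs(factorizedApprox(d0)), stateProbs(d0),
               tolerance = 1e-12)

  # marginals always preserved
  p <- fixtureParams3()
  d <- exactDistribution(p)
  fa <- factorizedApprox(d)
  expect_equal(stateMarginals(fa), stateMarginals(d), tolerance = 1e-12)

  # strong positive coupling: the product form puts more mass on the mixed
  # states (direct 4-state computation)
  ps <- boltzmannParams(matrix(c(0, 3, 3, 0), 2), c(0, 0))
  ds <- exactDistribution(ps)
  fs <- factorizedApprox(ds)
  mixed <- c(2, 3)                      # codes 1 and 2: states 10, 01
  expect_gt(sum(stateProbs(fs)[mixed]), sum(stateProbs(ds)[mixed]))
})

test_that("mass concentration count agrees with the sorted-cumsum oracle", {
  dU <- exactDistribution(boltzmannParams(matrix(0, 4, 4), rep(0, 4)))
  expect_equal(massConcentrationCount(dU, 1.0), 16L)

  peaked <- new("ExactDistribution",
                probs = c(0.95, rep(0.05 / 15, 15)), logZ = 0, K = 4L)
  expect_equal(massConcentrationCount(peaked, 0.9), 1L)

  set.seed(21)
  for (i in 1:5) {
    d <- exactDistribution(randomBoltzmann(4, 2.0))
    m <- massConcentrationCount(d, 0.9)
    sorted <- sort(stateProbs(d), decreasing = TRUE)
    expect_gte(sum(sorted[seq_len(m)]), 0.9 - 1e-12)
    if (m > 1) expect_lt(sum(sorted[seq_len(m - 1)]), 0.9)
  }
})
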