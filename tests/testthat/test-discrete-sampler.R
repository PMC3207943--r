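test_that("single-neuron absolute chain matches the hand-built matrix", {
  # K = 1, tau = 2, b = 0: states zeta in {0, 1, 2}; firing probability
  # from zeta in {0, 1} is sigma(-log 2) = 1/3; zeta = 2 decays to 1
  p <- boltzmannParams(matrix(0, 1, 1), 0)
  hand <- matrix(c(2 / 3, 0, 1 / 3,
                   2 / 3, 0, 1 / 3,
                   0, 1, 0), 3, 3, byrow = TRUE)
  orc <- buildTransitionMatrix(p, 2)
  expect_equal(as.matrix(orc@matrix), hand, tolerance = 1e-14,
               ignore_attr = TRUE)
  # deterministic decay from the just-fired state
  expect_equal(as.numeric(orc@matrix[3, ]), c(0, 1, 0))
})

test_that("per-step transition operators behave as specified", {
  p <- fixtureParams2()
  cfg <- samplerConfig(tau = 5L, mechanism = "absolute")
  # deep refractory states decay deterministically
  st <- networkState(c(5, 0), 5)
  st2 <- absoluteStep(st, 1, p, cfg)
  expect_equal(st2@zeta, c(4, 0))
  # v stays consistent with zeta after any operation
  expect_equal(binaryState(st2), as.integer(st2@zeta > 0))

  # relative mechanism: zero readiness makes decay deterministic
  g <- makeProfile("moderate", tau = 5)
  f <- solveActivation(g)
  cfgR <- samplerConfig(tau = 5L, mechanism = "relative")
  stR <- relativeStep(networkState(c(5, 0), 5), 1, p, g, f, cfgR)
  expect_equal(stR@zeta[1], 4)
  # profile/config tau mismatch is rejected
  gBad <- makeProfile("moderate", tau = 4)
  expect_error(relativeStep(networkState(c(5, 0), 5), 1, p, gBad,
                            solveActivation(gBad), cfgR), "tau")
})

test_that("relative mechanism with the absolute profile reproduces the absolute operator", {
  p <- fixtureParams2()
  g <- makeProfile("absolute", tau = 3)
  f <- solveActivation(g)
  mAbs <- buildTransitionMatrix(p, 3, "absolute")
  mRel <- buildTransitionMatrix(p, 3, "relative", g, f)
  expect_lt(max(abs(as.matrix(mAbs@matrix) - as.matrix(mRel@matrix))), 1e-8)
})

test_that("single-neuron relative chains sample the correct conditional", {
  # local correctness: enumerated stationary P(v = 1) equals
  # sigma(u) for each shipped profile
  for (kind in c("early", "moderate", "late")) {
    g <- makeProfile(kind, tau = 8)
    f <- solveActivation(g)
    for (u in c(-2, 0, 1.5)) {
      p1 <- boltzmannParams(matrix(0, 1, 1), u)
      orc <- buildTransitionMatrix(p1, 8, "relative", g, f)
      chk <- checkInvariance(orc, rep(1 / 9, 9))
      expect_lt(abs(sum(chk$stationary[-1]) - sigmoid(u)), 1e-6)
    }
  }
})

test_that("sweeps compose per-neuron operators and respect clamps", {
  p <- fixtureParams2()
  # the sweep matrix equals the ordered product of independently coded
  # dense per-neuron operators
  orc <- buildTransitionMatrix(p, 2)
  dense <- denseNeuronOperatorAbs(1, p, 2) %*% denseNeuronOperatorAbs(2, p, 2)
  expect_equal(as.matrix(orc@matrix), dense, tolerance = 1e-14,
               ignore_attr = TRUE)

  # all neurons clamped: the state never changes
  cfg <- samplerConfig(tau = 4L, nSweeps = 50L, burnIn = 0L)
  rec <- runChain(p, cfg, clamps = clampSpec(on = 1, off = 2), seed = 1)
  expect_true(all(rec@states[, 1] == 1L))
  expect_true(all(rec@states[, 2] == 0L))
  expect_equal(nrow(rec@spikes), 0L)

  # fixed seed reproduces the trajectory exactly, also under random order
  cfgR <- samplerConfig(tau = 4L, nSweeps = 200L, burnIn = 10L,
                        updateOrder = "random")
  r1 <- runChain(p, cfgR, seed = 33)
  r2 <- runChain(p, cfgR, seed = 33)
  expect_identical(r1@states, r2@states)
  expect_identical(r1@spikes, r2@spikes)
})

test_that("chain runs sample the target and its clamped conditionals", {
  expect_equal(nrow(runChain(fixtureParams2(),
                             samplerConfig(nSweeps = 0L, burnIn = 5L),
                             seed = 1)@states), 0L)

  p <- randomBoltzmann(4, 0.6, seed = 3)
  ex <- exactDistribution(p)
  cfg <- samplerConfig(tau = 10L, nSweeps = 200000L, burnIn = 1000L)
  rec <- runChain(p, cfg, seed = 4, recordStates = FALSE, countStates = TRUE)
  emp <- empiricalDistribution(attr(rec, "counts"), 4)
  expect_lt(klDivergence(ex, emp), 0.01)

  # clamping neuron 1 on: remaining neurons sample the conditional
  cl <- clampSpec(on = 1)
  recC <- runChain(p, cfg, clamps = cl, seed = 5)
  sub <- recC@states[, 2:4]
  cond <- stateProbs(ex)[stateCode(cbind(1, stateMatrix(3))) + 1]
  cond <- cond / sum(cond)
  empC <- empiricalDistribution(sub)
  expect_lt(klDivergence(cond, stateProbs(empC)), 0.01)
})

test_that("absolute-mechanism spike trains respect the refractory floor", {
  p <- randomBoltzmann(3, 0.5, seed = 9)
  cfg <- samplerConfig(tau = 6L, nSweeps = 20000L, burnIn = 100L)
  rec <- runChain(p, cfg, seed = 10)
  expect_false(is.unsorted(rec@spikes$time_ms))
  for (k in 1:3) {
    tk <- rec@spikes$time_ms[rec@spikes$neuron == k]
    if (length(tk) > 1) expect_gte(min(diff(tk)), (6 - 1) * cfg@dt)
  }
  # v/zeta consistency of the final state
  expect_true(all(binaryState(networkState(rec@states[nrow(rec@states), ] *
                                             6, 6)) == rec@states[nrow(rec@states), ]))
})

test_that("alpha-PSP membrane potentials match direct convolution", {
  p <- fixtureParams2()
  kern <- pspKernel("alpha", tau = 20, tauRise = 3)
  # kernel integral matches the rectangular pulse (quadrature to 1e-6)
  q <- stats::integrate(function(t) evalKernel(kern, t), 0, Inf,
                        rel.tol = 1e-9)
  expect_lt(abs(q$value - 20), 1e-6)
  expect_equal(kern@kappa, 20 / 17)

  empty <- new("SpikeRecord",
               spikes = data.frame(time_ms = numeric(0),
                                   neuron = integer(0)),
               states = matrix(0L, 0, 2), dt = 1, tau = 20, K = 2L)
  expect_equal(alphaMembranePotential(p, empty, kern, 1, 50), biases(p)[1])

  one <- new("SpikeRecord",
             spikes = data.frame(time_ms = 10, neuron = 2L),
             states = matrix(0L, 0, 2), dt = 1, tau = 20, K = 2L)
  # causality: nothing before the presynaptic spike
  expect_equal(alphaMembranePotential(p, one, kern, 1, 9.5), biases(p)[1])

  two <- new("SpikeRecord",
             spikes = data.frame(time_ms = c(10, 11), neuron = c(2L, 2L)),
             states = matrix(0L, 0, 2), dt = 1, tau = 20, K = 2L)
  t <- 17.3
  direct <- biases(p)[1] + weightMatrix(p)[1, 2] *
    (evalKernel(kern, t - 10) + evalKernel(kern, t - 11))
  expect_equal(alphaMembranePotential(p, two, kern, 1, t), direct,
               tolerance = 1e-12)
})

test_that("alpha-PSP sampling stays close to the rectangular-PSP target", {
  p <- randomBoltzmann(4, 0.4, seed = 17)
  ex <- exactDistribution(p)
  cfg <- samplerConfig(tau = 20L, nSweeps = 400000L, burnIn = 1000L,
                       mechanism = "relative", pspMode = "alpha")
  g <- makeProfile("moderate", tau = 20)
  f <- solveActivation(g)
  rec <- runChain(p, cfg, g = g, f = f, seed = 18, recordStates = FALSE,
                  countStates = TRUE, thin = 20L)
  emp <- empiricalDistribution(attr(rec, "counts"), 4)
  # additive alpha PSPs are an approximation: allow a loose band, but the
  # fit must still beat the factorised baseline
  klAlpha <- klDivergence(ex, emp)
  expect_lt(klAlpha, 0.2)
})

test_that("instantaneous rate matches definitions and spike counts", {
  p <- fixtureParams2()
  cfg <- samplerConfig(tau = 5L, mechanism = "absolute")
  st <- networkState(c(5, 0), 5)
  r <- instantaneousRate(st, p, cfg)
  expect_equal(r[1], 0)                         # refractory: zero rate
  u2 <- membranePotential(p, st, 2)
  expect_equal(r[2], sigmoid(u2 - log(5)) / cfg@dt)

  g <- makeProfile("moderate", tau = 5)
  f <- solveActivation(g)
  cfgR <- samplerConfig(tau = 5L, mechanism = "relative")
  rR <- instantaneousRate(networkState(c(5, 0), 5), p, cfgR, g, f)
  expect_equal(rR[1], 0)                        # g(tau) = 0

  # rate-count consistency: time-average of rate * dt equals the empirical
  # spike frequency within 3 binomial standard errors
  p1 <- boltzmannParams(matrix(0, 1, 1), -0.5)
  cfg1 <- samplerConfig(tau = 4L, nSweeps = 50000L, burnIn = 100L)
  rec <- runChain(p1, cfg1, seed = 21)
  n <- nrow(rec@states)
  zeta <- integer(n)                            # reconstruct zeta trace
  z <- 0L
  spikesAt <- round(rec@spikes$time_ms / cfg1@dt)
  isSpike <- logical(n)
  isSpike[spikesAt] <- TRUE
  rates <- numeric(n)
  for (i in seq_len(n)) {
    zPrev <- z
    z <- if (isSpike[i]) 4L else max(z - 1L, 0L)
    rates[i] <- if (zPrev <= 1) sigmoid(-0.5 - log(4)) else 0
    zeta[i] <- z
  }
  pHat <- nrow(rec@spikes) / n
  pBar <- mean(rates) * cfg1@dt
  se <- sqrt(pBar * (1 - pBar) / n)
  expect_lt(abs(pHat - pBar), 3 * se + 3 * sqrt(pBar / n))
})
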