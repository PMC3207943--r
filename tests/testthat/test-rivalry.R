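test_that("hexagonal grids have the right geometry and connectivity", {
  expect_equal(nrow(buildGrid(layers = 8, seed = 1)@coords), 217L)
  for (L in 1:4)
    expect_equal(nrow(buildGrid(layers = L, seed = 1)@coords),
                 1L + 3L * L * (L + 1L))

  # one layer at radius >= 2: everyone connected to everyone
  net1 <- buildGrid(layers = 1, connectionRadius = 2, seed = 2)
  expect_true(all(net1@mask[upper.tri(net1@mask)]))
  expect_equal(net1@mask, t(net1@mask))

  # nearest neighbours sit at unit distance
  net <- buildGrid(layers = 3, seed = 3)
  d <- as.matrix(dist(net@coords))
  expect_equal(min(d[d > 0]), 1, tolerance = 1e-12)

  # orientations cover [0, pi) with equal spacing
  phi <- sort(net@phiHat)
  expect_equal(phi, (seq_along(phi) - 1) * pi / length(phi),
               tolerance = 1e-12)
})

test_that("tuning curves peak at the preferred orientation and are periodic", {
  tun <- list(base = 0.03, contrast = 0.8, peak = 2)
  phiHat <- 0.7
  grid <- seq(0, pi, length.out = 181)
  vals <- tuningValue(grid, tun, phiHat)
  expect_equal(grid[which.max(vals)], phiHat, tolerance = 0.02)
  expect_equal(tuningValue(0.3, tun, phiHat),
               tuningValue(0.3 + pi, tun, phiHat), tolerance = 1e-12)
  # zero contrast: flat at the base sensitivity
  expect_equal(tuningValue(grid, list(base = 0.1, contrast = 0, peak = 2),
                           phiHat), rep(0.1, length(grid)))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("training patterns follow the tuning-curve generative model", {
  net <- buildGrid(layers = 2, seed = 4)
  # degenerate tuning: no activation at all
  net0 <- net; net0@tuning <- list(base = 0, contrast = 0, peak = 1)
  set.seed(5)
  expect_equal(sum(generateTrainingPattern(net0)$v), 0L)

  # activation frequency at fixed phi matches the tuning value within 3 SE
  set.seed(6)
  netP <- buildGrid(layers = 2, seed = 7)
  nRep <- 3000
  phiFix <- 1.1
  probs <- tuningValue(phiFix, netP@tuning, netP@phiHat)
  acts <- matrix(runif(nRep * length(probs)) <
                   rep(probs, each = nRep), nRep)
  # (direct binomial sanity on the same formula the generator uses)
  expect_lt(max(abs(colMeans(acts) - probs)),
            3 * sqrt(max(probs * (1 - probs)) / nRep) + 0.01)

  # orientation labels are uniform on [0, pi)
  set.seed(8)
  labs <- replicate(2000, generateTrainingPattern(netP)$phi)
  ks <- stats::ks.test(labs, "punif", 0, pi)
  expect_gt(ks$p.value, 0.01)
})

test_that("contrastive divergence respects the mask and symmetry", {
  net <- buildGrid(layers = 3, seed = 9)
  trained <- cdTrain(net, nPatterns = 500L, freeSteps = 10L, tau = 10L,
                     seed = 10)
  W <- weightMatrix(trained@params)
  expect_true(all(W[!trained@mask] == 0))
  expect_equal(W, t(W))
  expect_true(all(diag(W) == 0))
  # zero learning rate: parameters unchanged (fixed point of the update)
  frozen <- cdTrain(net, nPatterns = 200L, freeSteps = 5L, eta = 0,
                    tau = 10L, seed = 11)
  expect_equal(weightMatrix(frozen@params), weightMatrix(net@params))
  expect_equal(biases(frozen@params), biases(net@params))
})

test_that("population vectors follow the doubled-angle convention", {
  phiHat <- c(0, pi / 2, pi / 4)
  expect_equal(populationVector(c(0, 0, 0), phiHat), c(0, 0))
  # orthogonal orientations cancel
  expect_equal(populationVector(c(1, 1, 0), phiHat), c(0, 0),
               tolerance = 1e-12)
  expect_equal(populationVector(c(1, 0, 0), phiHat), c(1, 0))
  # matrix input matches row-wise evaluation
  S <- rbind(c(1, 0, 1), c(0, 1, 1))
  pv <- populationVector(S, phiHat)
  expect_equal(pv[1, ], populationVector(S[1, ], phiHat))
  expect_equal(pv[2, ], populationVector(S[2, ], phiHat))
})

test_that("switch detection is hysteretic", {
  mkPv <- function(angles, mag = 10) cbind(mag * cos(angles),
                                           mag * sin(angles))
  # alternating between the two region centers every 100 steps
  ang <- rep(rep(c(0, pi), each = 100), 5)
  sw <- detectSwitches(mkPv(ang), dt = 1)
  expect_true(all(abs(sw$durations_ms - 100) < 1e-9))

  # oscillation within one region: no switches
  angOsc <- 0.05 * sin(seq_len(500) / 10)
  expect_equal(length(detectSwitches(mkPv(angOsc))$switch_times_ms), 0L)

  # neutral-region excursions never change the switch count
  angBase <- rep(rep(c(0, pi), each = 100), 3)
  base <- detectSwitches(mkPv(angBase))
  angJit <- angBase
  angJit[seq(50, length(angJit), by = 37)] <- pi / 2     # dip into neutral
  jit <- detectSwitches(mkPv(angJit))
  expect_equal(length(jit$switch_times_ms), length(base$switch_times_ms))
  # low-magnitude excursions toward the far region are neutral too
  pvMag <- mkPv(angBase)
  pvMag[seq(60, nrow(pvMag), by = 41), ] <-
    mkPv(rep(pi, 1), mag = 0.1)[rep(1, length(seq(60, nrow(pvMag),
                                                  by = 41))), ]
  swMag <- detectSwitches(pvMag, magThreshold = 1)
  expect_equal(length(swMag$switch_times_ms),
               length(base$switch_times_ms))
})

test_that("gamma fitting recovers parameters and beats misuse", {
  set.seed(12)
  x <- rgamma(10000, shape = 3, scale = 2)
  fit <- gammaFit(x)
  expect_lt(abs(fit$shape - 3) / 3, 0.05)
  expect_lt(abs(fit$scale - 2) / 2, 0.05)

  # cross-check against the established MLE implementation
  if (requireNamespace("MASS", quietly = TRUE)) {
    ref <- MASS::fitdistr(x, "gamma")
    expect_equal(fit$shape, unname(ref$estimate["shape"]), tolerance = 1e-3)
  }

  # exponential data: shape ~ 1
  set.seed(13)
  e <- stats::rexp(10000, rate = 0.5)
  expect_lt(abs(gammaFit(e)$shape - 1), 0.05)

  # scale equivariance
  f1 <- gammaFit(x)
  f2 <- gammaFit(3 * x)
  expect_equal(f2$shape, f1$shape, tolerance = 1e-9)
  expect_equal(f2$scale, 3 * f1$scale, tolerance = 1e-9)

  expect_error(gammaFit(rep(1, 20)), "degenerate")
  expect_error(gammaFit(c(1, 2, 3)), "at least 10")
})

test_that("the ambiguous clamp leaves the documented free population", {
  net <- buildGrid(layers = 5, seed = 14)
  cl <- ambiguousClamp(net)
  expect_equal(length(cl@on), 4L)
  expect_equal(length(cl@off), 4L)
  expect_equal(anyDuplicated(c(cl@on, cl@off)), 0L)
  # clamped-on neurons are the ones tuned closest to the stimuli
  dOn <- abs(net@phiHat[cl@on] - rep(c(0, pi / 2), each = 2)) %% pi
  expect_true(all(pmin(dOn, pi - dOn) < 0.2))
})
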