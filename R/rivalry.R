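# Perceptual-rivalry demonstration: orientation-tuned hexagonal-grid
# network, contrastive-divergence training, population-vector decoding,
# switch detection and dominance-duration statistics.

#' Build an orientation-tuned hexagonal-grid network
#'
#' Neurons occupy a centered hexagon with `layers` rings around the central
#' site (site count 1 + 3 L (L+1); 8 layers give the full 217-neuron
#' network, 5 layers the scaled-down 91-neuron version).  Nearest
#' neighbours are at unit distance; any two neurons within
#' `connectionRadius` may form a synapse.  Preferred orientations cover
#' [0, pi) with equal spacing and are randomly assigned to grid positions.
#' Weights and biases start at zero.
#'
#' @param layers number of hexagonal rings (>= 1).
#' @param connectionRadius grid-distance cutoff for synapses.
#' @param tuning list with `base`, `contrast`, `peak` tuning parameters.
#' @param seed optional integer seed (controls orientation assignment).
#' @return A [RivalryNetwork-class] object.
#' @examples
#' net <- buildGrid(layers = 1, seed = 1)   # 7 neurons
#' @export
buildGrid <- function(layers = 5L, connectionRadius = 4,
                      tuning = list(base = 0.03, contrast = 0.8, peak = 2),
                      seed = NULL) {
  stopifnot(layers >= 1)
  if (!is.null(seed)) set.seed(seed)
  L <- as.integer(layers)
  ax <- expand.grid(q = -L:L, r = -L:L)
  ax <- ax[abs(ax$q + ax$r) <= L, ]
  coords <- cbind(x = ax$q + ax$r / 2, y = ax$r * sqrt(3) / 2)
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  mask <- d <= connectionRadius & d > 0
  phi <- sample((seq_len(n) - 1) * pi / n)
  params <- boltzmannParams(matrix(0, n, n), rep(0, n))
  new("RivalryNetwork", coords = coords, phiHat = phi, tuning = tuning,
      params = params, connectionRadius = connectionRadius, mask = mask)
}

#' Orientation tuning curve
#'
#' The pi-periodic activation probability of a neuron with preferred
#' orientation phiHat in response to a stimulus of orientation phi:
#' \deqn{tc(\phi) = a + c\, e^{p(\cos 2(\phi-\hat\phi) - 1)},}
#' clipped to [0, 1], with base sensitivity a, contrast c and peakedness p.
#' The curve is maximal at \eqn{\phi = \hat\phi} and reduces to the
#' constant a at zero contrast.
#'
#' @param phi stimulus orientation(s) in radians.
#' @param tuning list with `base`, `contrast`, `peak`.
#' @param phiHat preferred orientation(s).
#' @return activation probabilities in [0, 1].
#' @export
tuningValue <- function(phi, tuning, phiHat) {
  tc <- tuning$base +
    tuning$contrast * exp(tuning$peak * (cos(2 * (phi - phiHat)) - 1))
  pmin(pmax(tc, 0), 1)
}

#' Draw one training pattern from the tuning-curve generative model
#'
#' A global orientation phi is drawn uniformly from [0, pi); each neuron is
#' independently set active with probability equal to its tuning-curve
#' value at phi.  The resulting binary vector is a posterior sample for
#' contrastive-divergence training.
#'
#' @param network a [RivalryNetwork-class] object.
#' @return list with `v` (binary vector) and `phi` (orientation label).
#' @export
generateTrainingPattern <- function(network) {
  phi <- runif(1, 0, pi)
  p <- tuningValue(phi, network@tuning, network@phiHat)
  list(v = as.integer(runif(length(p)) < p), phi = phi)
}

#' Train the rivalry network with contrastive divergence
#'
#' For each pattern a posterior sample v+ is drawn from the tuning model;
#' the sampling network (relative refractory mechanism) is initialised at
#' v+ (refractory variables drawn uniformly from {1..tau} for active
#' neurons) and run freely for `freeSteps` sweeps to obtain v-; weights and
#' biases are updated by
#' \eqn{\Delta W_{kj} = \eta(v^+_k v^+_j - v^-_k v^-_j)} (applied
#' symmetrically inside the connectivity mask, diagonal fixed at zero) and
#' \eqn{\Delta b_k = \eta(v^+_k - v^-_k)}.
#'
#' @param network a [RivalryNetwork-class] object.
#' @param nPatterns number of training patterns.
#' @param freeSteps decorrelation sweeps of the negative phase.
#' @param eta learning rate.
#' @param tau refractory/PSP length in steps.
#' @param profile readiness-profile kind for the sampler.
#' @param seed optional integer seed.
#' @return the trained [RivalryNetwork-class].
#' @export
cdTrain <- function(network, nPatterns = 2e4L, freeSteps = 50L, eta = 0.01,
                    tau = 20L, profile = "moderate", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- makeProfile(profile, tau = tau)
  f <- solveActivation(g)
  res <- cpp_cd_train(network@params@W, network@params@b, network@mask,
                      network@phiHat, network@tuning$base,
                      network@tuning$contrast, network@tuning$peak,
                      as.integer(tau), profileValues(g), f@fValues,
                      f@uGrid[1], f@uGrid[2] - f@uGrid[1],
                      as.integer(nPatterns), as.integer(freeSteps), eta)
  network@params <- boltzmannParams(res$W, res$b)
  validObject(network)
  network
}

#' Population vector of a binary network state
#'
#' Sum over active neurons of the unit vector at the doubled preferred
#' orientation \eqn{2\hat\phi_k}; doubling makes orthogonal orientations
#' cancel and respects the pi-periodicity of orientation.  Returns (0, 0)
#' when no neuron is active.
#'
#' @param state binary 0/1 vector (or matrix, rows = states).
#' @param phiHat preferred orientations.
#' @return numeric length-2 vector, or an n x 2 matrix for matrix input.
#' @export
populationVector <- function(state, phiHat) {
  if (is.matrix(state)) {
    cbind(state %*% cos(2 * phiHat), state %*% sin(2 * phiHat))
  } else {
    c(sum(state * cos(2 * phiHat)), sum(state * sin(2 * phiHat)))
  }
}

#' Detect perceptual switches from a population-vector trajectory
#'
#' The population-vector plane is partitioned into two percept regions --
#' angular sectors of half-width `halfWidth` around the two doubled
#' stimulus directions -- intersected with a minimum-magnitude threshold,
#' plus a neutral remainder.  A switch is recorded when the trajectory
#' enters one percept region while the previously occupied percept region
#' was the other; excursions through the neutral region do not count
#' (hysteresis).  Dominance durations are the times between consecutive
#' switches.
#'
#' @param pv n x 2 matrix of population vectors (one row per time step).
#' @param stimAngles the two percept directions in the doubled-angle plane
#'   (radians); defaults to 0 and pi (stimulus orientations 0 and pi/2).
#' @param halfWidth angular half-width of each percept sector.
#' @param magThreshold minimum population-vector magnitude.
#' @param dt time per trajectory row in ms.
#' @return list with `durations_ms`, `switch_times_ms`, and the per-step
#'   `region` labels (1, 2 or 0 = neutral).
#' @export
detectSwitches <- function(pv, stimAngles = c(0, pi), halfWidth = pi / 8,
                           magThreshold = 0, dt = 1) {
  ang <- atan2(pv[, 2], pv[, 1])
  mag <- sqrt(rowSums(pv^2))
  circDist <- function(a, b) {
    d <- abs(a - b) %% (2 * pi)
    pmin(d, 2 * pi - d)
  }
  region <- integer(nrow(pv))
  inA <- circDist(ang, stimAngles[1]) <= halfWidth & mag >= magThreshold
  inB <- circDist(ang, stimAngles[2]) <= halfWidth & mag >= magThreshold
  region[inA] <- 1L
  region[inB] <- 2L
  switches <- numeric(0)
  last <- 0L
  for (i in seq_along(region)) {
    r <- region[i]
    if (r != 0L && r != last) {
      if (last != 0L) switches <- c(switches, i * dt)
      last <- r
    }
  }
  list(durations_ms = diff(switches), switch_times_ms = switches,
       region = region)
}

#' Maximum-likelihood Gamma fit of dominance durations
#'
#' Profile-likelihood estimation: for fixed shape the ML scale is
#' mean(x)/shape, and the remaining shape equation
#' \eqn{\log k - \psi(k) = \log \bar x - \overline{\log x}} is strictly
#' monotone in k, so a bracketed root search is globally safe.
#'
#' @param durations positive durations (>= 10 values required).
#' @param tol root tolerance on the shape.
#' @return list with `shape`, `scale` (= 1/rate), and the fitted-model
#'   log-likelihood `loglik`.
#' @importFrom stats uniroot dgamma
#' @export
gammaFit <- function(durations, tol = 1e-8) {
  if (length(durations) < 10) stop("need at least 10 durations")
  if (any(durations <= 0)) stop("durations must be positive")
  if (sd(durations) == 0) stop("degenerate (all-equal) durations")
  s <- log(mean(durations)) - mean(log(durations))   # > 0 unless degenerate
  fn <- function(k) log(k) - digamma(k) - s
  lo <- 1e-8; hi <- 1
  while (fn(hi) > 0) hi <- hi * 2                    # fn decreasing in k
  k <- uniroot(fn, c(lo, hi), tol = tol)$root
  theta <- mean(durations) / k
  list(shape = k, scale = theta,
       loglik = sum(dgamma(durations, shape = k, scale = theta, log = TRUE)))
}

#' Clamp specification for the ambiguous rivalry stimulus
#'
#' Two neurons whose preferred orientations are nearest each stimulus
#' orientation are clamped active (2 per stimulus), and two neurons nearest
#' each of the intermediate orientations (stimulus + pi/4, orthogonal to
#' the stimuli in the doubled-angle plane) are clamped inactive, for 8
#' clamped neurons in total.
#'
#' @param network a [RivalryNetwork-class] object.
#' @param stimOrientations the two stimulus orientations (radians in
#'   [0, pi)); default 0 and pi/2.
#' @return A [ClampSpec-class] object.
#' @export
ambiguousClamp <- function(network, stimOrientations = c(0, pi / 2)) {
  phi <- network@phiHat
  circDistPi <- function(a, b) {
    d <- abs(a - b) %% pi
    pmin(d, pi - d)
  }
  pickNearest <- function(target, n, exclude) {
    ord <- order(circDistPi(phi, target))
    setdiff(ord, exclude)[seq_len(n)]
  }
  on <- integer(0)
  for (s in stimOrientations) on <- c(on, pickNearest(s, 2L, on))
  off <- integer(0)
  for (s in stimOrientations + pi / 4)
    off <- c(off, pickNearest(s %% pi, 2L, c(on, off)))
  clampSpec(on = on, off = off)
}

#' Run the rivalry experiment
#'
#' (i) a free run of the trained network samples the prior over network
#' states; (ii) the ambiguous clamp (two stimuli of orthogonal orientation)
#' conditions the network, and the posterior trajectory over the unclamped
#' neurons is recorded; (iii) population vectors, perceptual switches,
#' dominance durations with a maximum-likelihood Gamma fit, and mean firing
#' rates are computed for both conditions.
#'
#' The percept regions use angular half-width pi/8 around each doubled
#' stimulus direction and a magnitude threshold of 25% of the 95th
#' percentile of the prior-run population-vector magnitude.
#'
#' @param network a trained [RivalryNetwork-class].
#' @param durationMs simulated duration per condition in ms.
#' @param tau,profile sampler settings (must match training).
#' @param stimOrientations the two stimulus orientations.
#' @param seed optional integer seed.
#' @return list with `prior` and `posterior` sub-lists (records, population
#'   vectors, rates), `clamp`, `durations_ms`, `gamma`, `exponential`
#'   (matched exponential fit), and `switch` diagnostics.
#' @importFrom stats dexp
#' @export
runRivalryExperiment <- function(network, durationMs = 6e4, tau = 20L,
                                 profile = "moderate",
                                 stimOrientations = c(0, pi / 2),
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- makeProfile(profile, tau = tau)
  f <- solveActivation(g)
  cfg <- samplerConfig(tau = tau, nSweeps = as.integer(durationMs),
                       burnIn = 1000L, mechanism = "relative")
  priorRec <- runChain(network@params, cfg, g = g, f = f)
  pvPrior <- populationVector(priorRec@states, network@phiHat)

  clamp <- ambiguousClamp(network, stimOrientations)
  postRec <- runChain(network@params, cfg, clamps = clamp, g = g, f = f)
  free <- setdiff(seq_len(length(network@params@b)),
                  c(clamp@on, clamp@off))
  pvPost <- populationVector(postRec@states[, free, drop = FALSE],
                             network@phiHat[free])

  magThr <- 0.25 * quantile(sqrt(rowSums(pvPrior^2)), 0.95)
  sw <- detectSwitches(pvPost, stimAngles = 2 * stimOrientations,
                       magThreshold = magThr, dt = cfg@dt)
  gfit <- efit <- NULL
  if (length(sw$durations_ms) >= 10) {
    gfit <- gammaFit(sw$durations_ms)
    rateHat <- 1 / mean(sw$durations_ms)
    efit <- list(rate = rateHat,
                 loglik = sum(dexp(sw$durations_ms, rateHat, log = TRUE)))
  }
  ratePrior <- firingStatistics(priorRec)$rate_hz
  ratePost <- firingStatistics(postRec)$rate_hz
  list(prior = list(record = priorRec, pv = pvPrior,
                    mean_rate_hz = mean(ratePrior)),
       posterior = list(record = postRec, pv = pvPost,
                        mean_rate_hz = mean(ratePost[free]),
                        free_neurons = free),
       clamp = clamp, durations_ms = sw$durations_ms, gamma = gfit,
       exponential = efit, switch = sw)
}

#' Similar- and dissimilar-orientation weight summary
#'
#' Mean trained weight among connected pairs with angular distance of
#' preferred orientations below pi/4 ("similar") and above ("dissimilar").
#'
#' @param network a trained [RivalryNetwork-class].
#' @return list with `similar_mean`, `dissimilar_mean`, and pair counts.
#' @export
weightsByOrientation <- function(network) {
  phi <- network@phiHat
  n <- length(phi)
  d <- abs(outer(phi, phi, "-")) %% pi
  d <- pmin(d, pi - d)
  up <- upper.tri(d) & network@mask
  sim <- up & d < pi / 4
  dis <- up & d >= pi / 4
  W <- network@params@W
  list(similar_mean = mean(W[sim]), dissimilar_mean = mean(W[dis]),
       n_similar = sum(sim), n_dissimilar = sum(dis))
}
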