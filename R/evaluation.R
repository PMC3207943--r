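# Sampler quality evaluation: Laplace-smoothed empirical distributions,
# KL divergence, the random-ensemble comparison of refractory mechanisms
# against the factorised baseline, and spike-train firing statistics.

#' Laplace-smoothed empirical distribution
#'
#' \eqn{\hat p(v) = (n_v + \alpha) / (N + \alpha 2^K)} with pseudo-count
#' \eqn{\alpha} added to every state's tally, guaranteeing strictly positive
#' probabilities.
#'
#' @param x either a matrix of 0/1 state snapshots (rows = samples) or a
#'   numeric count vector over all 2^K state codes.
#' @param K number of binary variables (required when `x` is a count
#'   vector; inferred from columns otherwise).
#' @param pseudoCount Laplace pseudo-count (> 0, default 1).
#' @return An [ExactDistribution-class] object.
#' @export
empiricalDistribution <- function(x, K = NULL, pseudoCount = 1) {
  stopifnot(pseudoCount > 0)
  if (is.matrix(x) && !is.null(dim(x)) && is.null(K)) K <- ncol(x)
  if (is.matrix(x)) {
    if (!is.null(K) && ncol(x) != K) stop("K mismatch")
    K <- ncol(x)
    counts <- tabulate(stateCode(x) + 1L, nbins = 2^K)
  } else {
    if (is.null(K)) stop("K required for count-vector input")
    if (length(x) != 2^K) stop("K mismatch")
    counts <- as.numeric(x)
  }
  N <- sum(counts)
  probs <- (counts + pseudoCount) / (N + pseudoCount * 2^K)
  new("ExactDistribution", probs = probs / sum(probs), logZ = 0,
      K = as.integer(K))
}

#' Kullback-Leibler divergence between two state distributions
#'
#' \eqn{D_{KL}(p\,\|\,q) = \sum_v p(v) \log(p(v)/q(v))} in nats; terms with
#' \eqn{p(v) = 0} contribute zero.  `q` must be strictly positive (which
#' Laplace smoothing guarantees).
#'
#' @param p,q [ExactDistribution-class] objects over the same K, or bare
#'   probability vectors of equal length.
#' @return the divergence in nats (>= 0 up to roundoff).
#' @export
klDivergence <- function(p, q) {
  pv <- if (is(p, "ExactDistribution")) p@probs else as.numeric(p)
  qv <- if (is(q, "ExactDistribution")) q@probs else as.numeric(q)
  if (length(pv) != length(qv)) stop("support mismatch")
  nz <- pv > 0
  sum(pv[nz] * (log(pv[nz]) - log(qv[nz])))
}

#' Finite-sample KL noise floor
#'
#' Draws `nRep` independent sets of `n` i.i.d. samples directly from the
#' exact distribution and reports the Laplace-smoothed KL of each empirical
#' estimate back to the truth: the divergence a *perfect* sampler shows at
#' this sample size.
#'
#' @param exact an [ExactDistribution-class] object.
#' @param n samples per replicate.
#' @param nRep number of replicates.
#' @param pseudoCount Laplace pseudo-count.
#' @param seed optional integer seed.
#' @return numeric vector of `nRep` KL values.
#' @importFrom stats rmultinom
#' @export
noiseFloorKL <- function(exact, n, nRep = 20L, pseudoCount = 1,
                         seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(nRep), function(i) {
    counts <- as.numeric(rmultinom(1, n, exact@probs))
    klDivergence(exact, empiricalDistribution(counts, exact@K, pseudoCount))
  }, numeric(1))
}

#' Random-ensemble comparison of refractory mechanisms
#'
#' For each weight scale in `sigmaWList`, draws `nDists` random Boltzmann
#' targets, runs each requested sampling mechanism, and reports the
#' Laplace-smoothed KL divergence to the exact target alongside the
#' analytic KL of the fully factorised baseline.  Samples are recorded with
#' spacing `thin` sweeps (default: one per refractory window tau) so that
#' the `nSamples` recorded states are close to independent.
#'
#' @param K variables per target (<= 20).
#' @param sigmaWList weight standard deviations (ensemble rows).
#' @param nDists random targets per weight scale.
#' @param nSamples recorded samples per run.
#' @param mechanisms subset of c("absolute", "relative").
#' @param relativeProfile profile kind for the relative mechanism.
#' @param tau refractory/PSP length in steps.
#' @param thin sweep spacing between recorded samples.
#' @param muB,sigmaB bias prior.
#' @param pseudoCount Laplace pseudo-count.
#' @param seed integer seed for the whole experiment.
#' @return data.frame with one row per (sigma_w, target, estimator) and
#'   columns `sigma_w`, `dist_id`, `estimator`, `kl`, `n_samples`.
#' @export
ensembleExperiment <- function(K = 10L, sigmaWList = c(0.03, 0.3, 3.0),
                               nDists = 20L, nSamples = 1e5L,
                               mechanisms = c("absolute", "relative"),
                               relativeProfile = "moderate", tau = 20L,
                               thin = tau, muB = -1.5, sigmaB = 0.5,
                               pseudoCount = 1, seed = 1L) {
  stopifnot(K <= 20)
  set.seed(seed)
  g <- makeProfile(relativeProfile, tau = tau)
  f <- solveActivation(g)
  rows <- list()
  for (sw in sigmaWList) {
    for (d in seq_len(nDists)) {
      params <- randomBoltzmann(K, sw, muB, sigmaB)
      exact <- exactDistribution(params)
      klFact <- klDivergence(exact, factorizedApprox(exact))
      rows[[length(rows) + 1L]] <-
        data.frame(sigma_w = sw, dist_id = d, estimator = "factorized",
                   kl = klFact, n_samples = NA_real_)
      for (mech in mechanisms) {
        cfg <- samplerConfig(tau = tau, nSweeps = as.integer(nSamples * thin),
                             burnIn = 1000L, mechanism = mech)
        rec <- runChain(params, cfg,
                        g = if (mech == "relative") g else NULL,
                        f = if (mech == "relative") f else NULL,
                        thin = thin, recordStates = FALSE,
                        countStates = TRUE)
        emp <- empiricalDistribution(attr(rec, "counts"), K, pseudoCount)
        rows[[length(rows) + 1L]] <-
          data.frame(sigma_w = sw, dist_id = d, estimator = mech,
                     kl = klDivergence(exact, emp),
                     n_samples = sum(attr(rec, "counts")))
      }
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- list(K = K, nSamples = nSamples, tau = tau,
                              thin = thin, relativeProfile = relativeProfile,
                              muB = muB, sigmaB = sigmaB,
                              pseudoCount = pseudoCount, seed = seed)
  out
}

#' Summarise an ensemble experiment as a mechanism-by-sigma table
#'
#' @param ensemble output of [ensembleExperiment()].
#' @return data.frame with rows = sigma_w, columns = mean and sd of KL per
#'   estimator.
#' @importFrom stats aggregate
#' @export
ensembleTable <- function(ensemble) {
  agg <- aggregate(kl ~ sigma_w + estimator, ensemble,
                   function(x) c(mean = mean(x), sd = sd(x)))
  out <- data.frame(sigma_w = agg$sigma_w, estimator = agg$estimator,
                    kl_mean = agg$kl[, "mean"], kl_sd = agg$kl[, "sd"])
  out[order(out$sigma_w, out$estimator), ]
}

#' Firing statistics of a spike record
#'
#' Per-neuron interspike intervals, coefficient of variation, and mean
#' firing rate; optionally the membrane-potential values of the recorded
#' state snapshots (for histogramming).
#'
#' @param record a [SpikeRecord-class] object.
#' @param params optional [BoltzmannParams-class]; if supplied and the
#'   record holds state snapshots, per-snapshot membrane potentials are
#'   returned as well.
#' @param duration recording duration in ms (defaults to the span implied
#'   by the record).
#' @return list with `isi` (list of per-neuron ISI vectors, ms), `cv`
#'   (per-neuron; NA with fewer than 2 spikes), `rate_hz` (per-neuron mean
#'   rate), and `u` (matrix of membrane potentials or NULL).
#' @export
firingStatistics <- function(record, params = NULL, duration = NULL) {
  K <- record@K
  sp <- record@spikes
  if (is.null(duration)) {
    duration <- if (nrow(record@states) && !is.na(record@dt))
      nrow(record@states) * record@dt
    else if (nrow(sp)) max(sp$time_ms) else 0
  }
  isi <- vector("list", K)
  cv <- rep(NA_real_, K)
  rate <- rep(0, K)
  for (k in seq_len(K)) {
    tk <- sp$time_ms[sp$neuron == k]
    if (length(tk) >= 2L) {
      d <- diff(tk)
      isi[[k]] <- d
      cv[k] <- sd(d) / mean(d)
    } else isi[[k]] <- numeric(0)
    if (duration > 0) rate[k] <- length(tk) / duration * 1000
  }
  u <- NULL
  if (!is.null(params) && nrow(record@states))
    u <- membranePotentialTrace(params, record@states)
  list(isi = isi, cv = cv, rate_hz = rate, u = u)
}
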