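# Continuous-time neural sampling: exact event-driven simulation of the
# Markov jump process with the absolute refractory mechanism.  Resting
# neurons fire as Poisson processes with rate exp(u_k)/tau (the rate whose
# renewal process has active fraction sigma(u_k)); refractory variables
# decay linearly and recoveries are scheduled events; rates are piecewise
# constant between events, so competing exponential clocks are exact.

#' Run the continuous-time jump process
#'
#' @param params a [BoltzmannParams-class] object.
#' @param tauMs PSP/refractory duration in ms.
#' @param tTotal simulated duration in ms (after burn-in).
#' @param burnIn initial duration discarded, in ms.
#' @param seed optional integer seed.
#' @param trackOccupancy accumulate time-weighted occupancy of the 2^K
#'   binary states (requires K <= 20).
#' @return A [SpikeRecord-class] with continuous spike times (dt = NA);
#'   attributes "occupancy" (time in ms spent in each binary state code)
#'   and "active_ms" (per-neuron total active time).
#' @export
runJumpProcess <- function(params, tauMs = 20, tTotal = 1e5, burnIn = 1000,
                           seed = NULL, trackOccupancy = TRUE) {
  if (tTotal <= 0) stop("tTotal must be > 0")
  if (!is.null(seed)) set.seed(seed)
  res <- cpp_jump_process(params@W, params@b, tauMs, tTotal, burnIn,
                          TRUE, trackOccupancy)
  rec <- new("SpikeRecord",
             spikes = data.frame(time_ms = res$spike_t,
                                 neuron = res$spike_id),
             states = matrix(0L, 0, nNeurons(params)),
             dt = NA_real_, tau = tauMs, K = as.integer(nNeurons(params)))
  attr(rec, "occupancy") <- res$occupancy
  attr(rec, "active_ms") <- res$active_ms
  rec
}

#' Time-weighted empirical distribution of a jump-process run
#'
#' Laplace-smoothed distribution over binary states from the occupancy
#' attribute of [runJumpProcess()]: occupancy times play the role of counts
#' after normalising total time to an effective sample count `nEff`.
#'
#' @param record a [SpikeRecord-class] from [runJumpProcess()].
#' @param pseudoCount Laplace pseudo-count.
#' @param nEff effective number of samples assigned to the total simulated
#'   time (defaults to total time / tau, one per renewal window).
#' @return An [ExactDistribution-class] object.
#' @export
occupancyDistribution <- function(record, pseudoCount = 1, nEff = NULL) {
  occ <- attr(record, "occupancy")
  if (is.null(occ)) stop("record has no occupancy attribute")
  K <- record@K
  if (is.null(nEff)) nEff <- sum(occ) / record@tau
  counts <- occ / sum(occ) * nEff
  probs <- (counts + pseudoCount) / (nEff + pseudoCount * 2^K)
  new("ExactDistribution", probs = probs / sum(probs), logZ = 0,
      K = as.integer(K))
}

#' Discretisation consistency report
#'
#' Runs the discrete-time absolute-mechanism chain at a sequence of step
#' sizes (holding the PSP duration fixed in ms, so tau = tauMs/dt steps) and
#' the continuous-time jump process on the same target, and reports the
#' Laplace-smoothed KL divergence of each empirical distribution to the
#' exact target.  As dt shrinks the discrete chain approaches the jump
#' process, so the KL sequence approaches the continuous-chain value up to
#' Monte-Carlo noise.
#'
#' @param params a [BoltzmannParams-class] object (K <= 20).
#' @param tauMs PSP duration in ms.
#' @param dtSequence decreasing step sizes in ms; each must divide tauMs.
#' @param tTotal simulated duration per run in ms.
#' @param seed integer seed (one stream reused per run in sequence).
#' @param pseudoCount Laplace pseudo-count.
#' @return data.frame with columns `dt` (NA for the continuous run),
#'   `tau_steps`, `n_samples` and `kl`.
#' @export
discretizationConsistency <- function(params, tauMs = 20,
                                      dtSequence = c(4, 2, 1),
                                      tTotal = 2e5, seed = 1,
                                      pseudoCount = 1) {
  stopifnot(all(abs(tauMs / dtSequence - round(tauMs / dtSequence)) < 1e-9))
  set.seed(seed)
  exact <- exactDistribution(params)
  rows <- list()
  for (dt in dtSequence) {
    tauSteps <- as.integer(round(tauMs / dt))
    nSweeps <- as.integer(round(tTotal / dt))
    cfg <- samplerConfig(tau = tauSteps, dt = dt, nSweeps = nSweeps,
                         burnIn = as.integer(round(1000 / dt)),
                         mechanism = "absolute")
    rec <- runChain(params, cfg, recordStates = FALSE, countStates = TRUE,
                    thin = tauSteps)
    emp <- empiricalDistribution(attr(rec, "counts"), nNeurons(params),
                                 pseudoCount)
    rows[[length(rows) + 1L]] <-
      data.frame(dt = dt, tau_steps = tauSteps,
                 n_samples = sum(attr(rec, "counts")),
                 kl = klDivergence(exact, emp))
  }
  recC <- runJumpProcess(params, tauMs = tauMs, tTotal = tTotal)
  empC <- occupancyDistribution(recC, pseudoCount)
  rows[[length(rows) + 1L]] <-
    data.frame(dt = NA_real_, tau_steps = NA_integer_,
               n_samples = round(tTotal / tauMs),
               kl = klDivergence(exact, empC))
  do.call(rbind, rows)
}
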