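# Discrete-time neural sampling chain: per-neuron transition operators,
# full-network sweeps, chain runs with spike recording, and the additive
# alpha-PSP membrane-potential variant.

.clampVector <- function(clamps, K) {
  cl <- rep(-1L, K)
  if (!is.null(clamps)) {
    if (length(c(clamps@on, clamps@off)) &&
        max(c(clamps@on, clamps@off, 0L)) > K)
      stop("clamp index out of range")
    cl[clamps@on] <- 1L
    cl[clamps@off] <- 0L
  }
  cl
}

.checkActivation <- function(config, g, f) {
  if (config@mechanism == "relative") {
    if (is.null(g) || is.null(f))
      stop("relative mechanism requires a profile g and solved activation f")
    if (profileTau(g) != config@tau)
      stop("profile tau does not match sampler tau")
    if (profileTau(f@profile) != profileTau(g) ||
        any(f@profile@values != g@values))
      stop("activation function was solved for a different profile")
  }
  invisible(TRUE)
}

#' Single update of one neuron, absolute refractory mechanism
#'
#' In the resting state (zeta = 0) or the last refractory state (zeta = 1)
#' the neuron spikes with probability \eqn{\sigma(u_k - \log\tau)}; a spike
#' sets zeta to tau, otherwise zeta falls to 0.  Deeper refractory states
#' decay deterministically by one.  All other neurons are untouched.
#'
#' @param state a [NetworkState-class] object.
#' @param k neuron index.
#' @param params a [BoltzmannParams-class] object.
#' @param config a [SamplerConfig-class] with `mechanism = "absolute"`.
#' @return the updated [NetworkState-class].
#' @export
absoluteStep <- function(state, k, params, config) {
  stopifnot(config@mechanism == "absolute")
  z <- state@zeta[k]
  if (z > 1) {
    state@zeta[k] <- z - 1
  } else {
    u <- membranePotential(params, state, k)
    spike <- runif(1) < sigmoid(u - log(config@tau))
    state@zeta[k] <- if (spike) config@tau else 0
  }
  state
}

#' Single update of one neuron, relative refractory mechanism
#'
#' From any state the neuron re-fires with probability
#' \eqn{g(\zeta_k) f(u_k)} (g(0) = 1 at rest); a spike resets zeta to tau,
#' otherwise zeta decays by one (or stays at 0).
#'
#' @param state a [NetworkState-class] object.
#' @param k neuron index.
#' @param params a [BoltzmannParams-class] object.
#' @param g a [RefractoryProfile-class].
#' @param f the matched [ActivationFunction-class] solved for `g`.
#' @param config a [SamplerConfig-class] with `mechanism = "relative"`.
#' @return the updated [NetworkState-class].
#' @export
relativeStep <- function(state, k, params, g, f, config) {
  stopifnot(config@mechanism == "relative")
  .checkActivation(config, g, f)
  z <- state@zeta[k]
  gz <- profileValues(g)[z + 1]
  u <- membranePotential(params, state, k)
  pFire <- gz * evalActivation(f, u)
  if (runif(1) < pFire) state@zeta[k] <- config@tau
  else state@zeta[k] <- max(z - 1, 0)
  state
}

#' One full sweep over the network
#'
#' Applies the per-neuron operator to every unclamped neuron once, in the
#' configured order, each update seeing the most recent refractory variables
#' of all other neurons.
#'
#' @inheritParams relativeStep
#' @param clamps an optional [ClampSpec-class].
#' @return the updated [NetworkState-class].
#' @export
sweepStep <- function(state, params, config, clamps = NULL, g = NULL,
                      f = NULL) {
  K <- nNeurons(params)
  cl <- .clampVector(clamps, K)
  ord <- if (config@updateOrder == "random") sample.int(K) else seq_len(K)
  for (k in ord) {
    if (cl[k] >= 0) next
    state <- if (config@mechanism == "absolute")
      absoluteStep(state, k, params, config)
    else relativeStep(state, k, params, g, f, config)
  }
  state
}

#' Run the discrete-time sampling chain
#'
#' Initialises all neurons at rest (zeta = 0, or clamped values), runs
#' `burnIn` sweeps followed by `nSweeps` recorded sweeps, and returns the
#' spikes together with one binary state snapshot per `thin` sweeps.  With
#' `pspMode = "alpha"` the membrane potential is computed from the additive
#' alpha-shaped PSP traces of the spike history instead of the rectangular
#' renewal value, while the sampled binary state remains defined by the
#' refractory variables.
#'
#' @param params a [BoltzmannParams-class] object.
#' @param config a [SamplerConfig-class] object.
#' @param clamps an optional [ClampSpec-class].
#' @param g,f readiness profile and matched activation function (required
#'   for the relative mechanism).
#' @param kernel [PSPKernel-class] for `pspMode = "alpha"` (defaults to the
#'   integral-matched alpha kernel for the configured tau).
#' @param seed optional integer seed.
#' @param thin snapshot spacing in sweeps (1 = every sweep).
#' @param recordStates,countStates whether to keep snapshots and/or a
#'   2^K state-count table (counting requires K <= 20).
#' @param zetaInit optional initial refractory vector.
#' @return A [SpikeRecord-class]; if `countStates`, the count table is
#'   attached as attribute "counts".
#' @export
runChain <- function(params, config, clamps = NULL, g = NULL, f = NULL,
                     kernel = NULL, seed = NULL, thin = 1L,
                     recordStates = TRUE, countStates = FALSE,
                     zetaInit = NULL) {
  if (!is.null(seed)) set.seed(seed)
  .checkActivation(config, g, f)
  K <- nNeurons(params)
  cl <- .clampVector(clamps, K)
  if (config@pspMode == "alpha" && is.null(kernel))
    kernel <- pspKernel("alpha", tau = config@tau * config@dt)
  gv <- if (is.null(g)) numeric(config@tau + 1) else profileValues(g)
  fv <- if (is.null(f)) numeric(0) else f@fValues
  fu0 <- if (is.null(f)) 0 else f@uGrid[1]
  fstep <- if (is.null(f)) 1 else f@uGrid[2] - f@uGrid[1]
  res <- cpp_run_chain(
    params@W, params@b, config@tau, config@nSweeps, config@burnIn,
    if (config@mechanism == "absolute") 0L else 1L,
    gv, fv, fu0, fstep, cl, config@updateOrder == "random",
    as.integer(thin), config@dt, TRUE, recordStates, countStates,
    if (config@pspMode == "alpha") 1L else 0L,
    if (is.null(kernel)) 1 else kernel@kappa,
    if (is.null(kernel)) 1 else kernel@tauRise,
    if (is.null(kernel)) config@tau * config@dt else kernel@tauFall,
    if (is.null(zetaInit)) numeric(0) else as.numeric(zetaInit))
  states <- if (recordStates) res$states else matrix(0L, 0, K)
  rec <- new("SpikeRecord",
             spikes = data.frame(time_ms = res$spike_t,
                                 neuron = res$spike_id),
             states = states, dt = config@dt, tau = as.numeric(config@tau),
             K = as.integer(K))
  if (countStates) attr(rec, "counts") <- res$counts
  rec
}

#' Membrane potential under additive alpha-shaped PSPs
#'
#' Evaluates \eqn{u_k(t) = b_k + \sum_{j\neq k} W_{kj} \sum_{s \in S_j}
#' \epsilon(t - s)} directly from a spike history, with PSPs from the same
#' synapse summing additively.
#'
#' @param params a [BoltzmannParams-class] object.
#' @param record a [SpikeRecord-class] holding the presynaptic spikes.
#' @param kernel a [PSPKernel-class].
#' @param k postsynaptic neuron index.
#' @param t evaluation time in ms.
#' @return the membrane potential u_k(t).
#' @export
alphaMembranePotential <- function(params, record, kernel, k, t) {
  sp <- record@spikes
  u <- params@b[k]
  if (nrow(sp) == 0) return(u)
  for (j in seq_len(record@K)) {
    if (j == k) next
    tj <- sp$time_ms[sp$neuron == j]
    if (length(tj)) u <- u + params@W[k, j] * sum(evalKernel(kernel, t - tj))
  }
  u
}

#' Instantaneous firing rate of each neuron
#'
#' The per-step firing probability divided by the step duration:
#' \eqn{g(\zeta_k) f(u_k) / \Delta t} for the relative mechanism, and
#' \eqn{\sigma(u_k - \log\tau)/\Delta t} in the firing-capable states of the
#' absolute mechanism (0 while refractory).
#'
#' @param state a [NetworkState-class] object.
#' @param params a [BoltzmannParams-class] object.
#' @param config a [SamplerConfig-class] object.
#' @param g,f profile and activation function for the relative mechanism.
#' @return numeric vector of rates in spikes/ms.
#' @export
instantaneousRate <- function(state, params, config, g = NULL, f = NULL) {
  K <- nNeurons(params)
  v <- binaryState(state)
  u <- params@b + as.numeric(params@W %*% v)
  if (config@mechanism == "absolute") {
    p <- ifelse(state@zeta <= 1, sigmoid(u - log(config@tau)), 0)
  } else {
    .checkActivation(config, g, f)
    gz <- profileValues(g)[state@zeta + 1]
    p <- gz * evalActivation(f, u)
  }
  p / config@dt
}
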