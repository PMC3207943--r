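#' @import methods
#' @importFrom stats rnorm runif sd setNames quantile
NULL

# ---------------------------------------------------------------------------
# Central S4 classes.  All state-space indexing in the package uses a single
# convention: a binary vector v in {0,1}^K is coded as the integer
# sum_k v_k 2^(k-1) (neuron 1 is the least-significant bit), and probability
# tables are stored as plain numeric vectors in that order.
# ---------------------------------------------------------------------------

#' Boltzmann distribution parameters
#'
#' Holds the parameters of a Boltzmann distribution over K binary variables,
#' \deqn{p(v) \propto \exp\left(\sum_k b_k v_k +
#'   \tfrac{1}{2}\sum_{k,j} W_{kj} v_k v_j\right),}
#' with a symmetric, zero-diagonal weight matrix \eqn{W} and a bias
#' (excitability) vector \eqn{b}.  In the sampling-network interpretation
#' \eqn{W_{kj}} is the synaptic weight between neurons \eqn{k} and \eqn{j}
#' and \eqn{b_k} the excitability of neuron \eqn{k}.
#'
#' @slot W symmetric K x K numeric matrix with zero diagonal.
#' @slot b numeric vector of length K.
#' @export
setClass("BoltzmannParams", representation(W = "matrix", b = "numeric"))

setValidity("BoltzmannParams", function(object) {
  W <- object@W; b <- object@b
  if (!is.numeric(W) || nrow(W) != ncol(W))
    return("W must be a square numeric matrix")
  if (length(b) != nrow(W))
    return("length(b) must equal nrow(W)")
  if (nrow(W) < 1L) return("need at least one variable (K >= 1)")
  if (!all(is.finite(W)) || !all(is.finite(b)))
    return("all parameters must be finite")
  if (any(diag(W) != 0)) return("diagonal of W must be exactly zero")
  if (!isTRUE(all.equal(W, t(W), tolerance = 0, check.attributes = FALSE)))
    return("W must be exactly symmetric")
  TRUE
})

#' Construct Boltzmann distribution parameters
#'
#' @param W symmetric numeric weight matrix with zero diagonal.
#' @param b numeric bias vector, one entry per variable.
#' @return A [BoltzmannParams-class] object.
#' @examples
#' boltzmannParams(matrix(c(0, 1, 1, 0), 2), c(-1, 0.5))
#' @export
boltzmannParams <- function(W, b) {
  W <- as.matrix(W)
  storage.mode(W) <- "double"
  dimnames(W) <- NULL
  new("BoltzmannParams", W = W, b = as.numeric(b))
}

#' @describeIn boltzmannParams number of binary variables / neurons K.
#' @param params a [BoltzmannParams-class] object.
#' @export
nNeurons <- function(params) length(params@b)

#' @describeIn boltzmannParams the weight matrix W.
#' @export
weightMatrix <- function(params) params@W

#' @describeIn boltzmannParams the bias vector b.
#' @export
biases <- function(params) params@b

setMethod("show", "BoltzmannParams", function(object) {
  K <- nNeurons(object)
  cat(sprintf("BoltzmannParams over %d binary variables\n", K))
  off <- object@W[upper.tri(object@W)]
  cat(sprintf("  weights: sd %.3g, range [%.3g, %.3g]\n",
              if (length(off)) sd(off) else 0,
              if (length(off)) min(off) else 0,
              if (length(off)) max(off) else 0))
  cat(sprintf("  biases : mean %.3g, range [%.3g, %.3g]\n",
              mean(object@b), min(object@b), max(object@b)))
})

#' Exact distribution over binary states
#'
#' Probability table over all 2^K binary states, indexed by the integer code
#' of the state (neuron 1 = least-significant bit), together with the log
#' normalisation constant of the unnormalised Boltzmann weights.
#'
#' @slot probs numeric vector of length 2^K, strictly positive, summing to 1.
#' @slot logZ log of the partition function.
#' @slot K integer, number of binary variables.
#' @export
setClass("ExactDistribution",
         representation(probs = "numeric", logZ = "numeric", K = "integer"))

setValidity("ExactDistribution", function(object) {
  if (length(object@probs) != 2^object@K)
    return("probs must have length 2^K")
  if (any(object@probs <= 0))
    return("all state probabilities must be strictly positive")
  if (abs(sum(object@probs) - 1) > 1e-12)
    return("probabilities must sum to 1 within 1e-12")
  TRUE
})

setMethod("show", "ExactDistribution", function(object) {
  cat(sprintf("ExactDistribution over %d states (K = %d), logZ = %.6g\n",
              length(object@probs), object@K, object@logZ))
})

#' @describeIn exactDistribution extract the probability table (numeric
#'   vector over state codes 0..2^K-1).
#' @param x an [ExactDistribution-class] object.
#' @export
stateProbs <- function(x) x@probs

#' Network state of the sampling chain
#'
#' Per-neuron refractory variables zeta.  \eqn{\zeta_k \in \{0,\dots,\tau\}}
#' in discrete time (nonnegative reals in continuous time); the binary
#' variable is derived as \eqn{v_k = 1 \iff \zeta_k > 0}.
#'
#' @slot zeta numeric vector of refractory variables.
#' @slot tau refractory/PSP duration (steps in discrete time, ms in
#'   continuous time).
#' @export
setClass("NetworkState", representation(zeta = "numeric", tau = "numeric"))

setValidity("NetworkState", function(object) {
  if (object@tau < 1) return("tau must be >= 1")
  if (any(object@zeta < 0) || any(object@zeta > object@tau))
    return("zeta values must lie in [0, tau]")
  TRUE
})

#' @rdname NetworkState-class
#' @param zeta numeric vector of refractory variables.
#' @param tau refractory duration.
#' @export
networkState <- function(zeta, tau) new("NetworkState", zeta = as.numeric(zeta),
                                        tau = as.numeric(tau))

#' Binary state derived from the refractory variables
#'
#' @param state a [NetworkState-class] object.
#' @return integer 0/1 vector, \eqn{v_k = [\zeta_k > 0]}.
#' @export
binaryState <- function(state) as.integer(state@zeta > 0)

setMethod("show", "NetworkState", function(object) {
  cat(sprintf("NetworkState: K = %d, tau = %g, active %d\n",
              length(object@zeta), object@tau, sum(object@zeta > 0)))
})

#' Joint distribution over binary states and refractory variables
#'
#' The augmented target of the discrete-time sampler: a probability table
#' over all (tau+1)^K configurations of the refractory variables zeta.  The
#' state with index code \eqn{\sum_k \zeta_k (\tau+1)^{k-1}} corresponds to
#' the configuration zeta.  Conditioned on \eqn{v_k = 1}, \eqn{\zeta_k} is
#' uniform on \eqn{\{1,\dots,\tau\}}; conditioned on \eqn{v_k = 0} it is 0.
#'
#' @slot probs numeric vector of length (tau+1)^K.
#' @slot K integer number of neurons.
#' @slot tau integer refractory length.
#' @export
setClass("JointAuxDistribution",
         representation(probs = "numeric", K = "integer", tau = "integer"))

setValidity("JointAuxDistribution", function(object) {
  if (length(object@probs) != (object@tau + 1L)^object@K)
    return("probs must have length (tau+1)^K")
  if (abs(sum(object@probs) - 1) > 1e-12)
    return("probabilities must sum to 1 within 1e-12")
  TRUE
})

setMethod("show", "JointAuxDistribution", function(object) {
  cat(sprintf("JointAuxDistribution: K = %d, tau = %d, %d joint states\n",
              object@K, object@tau, length(object@probs)))
})

#' Refractory readiness profile
#'
#' The readiness function g of the relative refractory mechanism, tabulated
#' over the refractory states \eqn{\zeta \in \{1,\dots,\tau\}} (slot
#' `values`, ordered by zeta).  By convention the resting state has full
#' readiness, \eqn{g(0) = 1}.  The just-fired state must have zero readiness,
#' \eqn{g(\tau) = 0}, and at least one refractory state must have positive
#' readiness.  Values are restricted to [0, 1] so that g(zeta) f(u) is a
#' probability for any activation value f(u) in (0, 1).
#'
#' @slot values numeric vector g(1), ..., g(tau).
#' @slot kind character label ("absolute", "early", "moderate", "late",
#'   or "table").
#' @export
setClass("RefractoryProfile",
         representation(values = "numeric", kind = "character"))

setValidity("RefractoryProfile", function(object) {
  g <- object@values
  if (length(g) < 1L) return("profile needs tau >= 1 refractory states")
  if (!all(is.finite(g)) || any(g < 0)) return("g values must be finite and >= 0")
  if (any(g > 1)) return("g values must be <= 1")
  if (g[length(g)] != 0) return("g(tau) must be 0 (just-fired state cannot re-fire)")
  if (length(g) > 1L && all(g == 0)) return("at least one readiness value must be > 0")
  TRUE
})

#' @describeIn makeProfile refractory length tau of a profile.
#' @export
profileTau <- function(g) length(g@values)

#' @describeIn makeProfile readiness values g(zeta) for zeta = 0, ..., tau
#'   (g(0) = 1 prepended).
#' @export
profileValues <- function(g) c(1, g@values)

setMethod("show", "RefractoryProfile", function(object) {
  cat(sprintf("RefractoryProfile '%s': tau = %d, g(1..tau) = %s\n",
              object@kind, length(object@values),
              paste(signif(object@values, 3), collapse = " ")))
})

#' Tabulated activation function
#'
#' The firing function f(u) matched to a refractory readiness profile g so
#' that the single-neuron chain samples its binary variable from the correct
#' conditional distribution (stationary \eqn{P(v=1) = \sigma(u)}).  Values
#' are tabulated on a regular u-grid and looked up with piecewise-constant
#' (nearest-node) interpolation.
#'
#' @slot uGrid sorted numeric grid of membrane-potential values.
#' @slot fValues solved f at the grid nodes, each in (0, 1).
#' @slot profile the [RefractoryProfile-class] the function was solved for.
#' @slot tol root-finding tolerance used by the solver.
#' @export
setClass("ActivationFunction",
         representation(uGrid = "numeric", fValues = "numeric",
                        profile = "RefractoryProfile", tol = "numeric"))

setValidity("ActivationFunction", function(object) {
  if (length(object@uGrid) != length(object@fValues))
    return("uGrid and fValues must have equal length")
  if (is.unsorted(object@uGrid, strictly = TRUE))
    return("uGrid must be strictly increasing")
  if (any(object@fValues <= 0) || any(object@fValues >= 1))
    return("f values must lie strictly in (0, 1)")
  if (is.unsorted(object@fValues))
    return("f must be monotonically nondecreasing")
  TRUE
})

setMethod("show", "ActivationFunction", function(object) {
  cat(sprintf(
    "ActivationFunction for profile '%s' (tau = %d): %d grid nodes on [%g, %g]\n",
    object@profile@kind, profileTau(object@profile),
    length(object@uGrid), min(object@uGrid), max(object@uGrid)))
})

#' Clamp specification
#'
#' Neurons clamped to observed binary values: clamped-on neurons are frozen
#' at zeta = tau (v = 1), clamped-off neurons at zeta = 0 (v = 0), and their
#' update operators are skipped, so the remaining neurons sample from the
#' conditional distribution given the observations.
#'
#' @slot on integer indices of neurons clamped to 1.
#' @slot off integer indices of neurons clamped to 0.
#' @export
setClass("ClampSpec", representation(on = "integer", off = "integer"))

setValidity("ClampSpec", function(object) {
  idx <- c(object@on, object@off)
  if (anyDuplicated(idx)) return("clamp indices must be unique")
  if (length(idx) && (any(idx < 1L))) return("clamp indices must be >= 1")
  TRUE
})

#' @rdname ClampSpec-class
#' @param on integer indices of neurons clamped active.
#' @param off integer indices of neurons clamped inactive.
#' @export
clampSpec <- function(on = integer(0), off = integer(0))
  new("ClampSpec", on = as.integer(on), off = as.integer(off))

setMethod("show", "ClampSpec", function(object) {
  cat(sprintf("ClampSpec: %d on, %d off\n",
              length(object@on), length(object@off)))
})

#' Sampler configuration
#'
#' @slot tau integer refractory/PSP length in steps (>= 1).
#' @slot dt duration of one step in ms.
#' @slot nSweeps number of recorded sweeps.
#' @slot burnIn number of burn-in sweeps discarded before recording.
#' @slot updateOrder "fixed" (ascending index every sweep) or "random"
#'   (fresh permutation per sweep).
#' @slot mechanism "absolute" or "relative".
#' @slot pspMode "rect" (rectangular renewal PSPs) or "alpha" (additive
#'   alpha-shaped PSPs entering the membrane potential).
#' @export
setClass("SamplerConfig",
         representation(tau = "integer", dt = "numeric", nSweeps = "integer",
                        burnIn = "integer", updateOrder = "character",
                        mechanism = "character", pspMode = "character"))

setValidity("SamplerConfig", function(object) {
  if (object@tau < 1L) return("tau must be >= 1")
  if (object@dt <= 0) return("dt must be > 0")
  if (object@nSweeps < 0L || object@burnIn < 0L)
    return("sweep counts must be >= 0")
  if (!object@updateOrder %in% c("fixed", "random"))
    return("updateOrder must be 'fixed' or 'random'")
  if (!object@mechanism %in% c("absolute", "relative"))
    return("mechanism must be 'absolute' or 'relative'")
  if (!object@pspMode %in% c("rect", "alpha"))
    return("pspMode must be 'rect' or 'alpha'")
  TRUE
})

#' Construct a sampler configuration
#'
#' Defaults follow the millisecond interpretation of an MCMC step: dt = 1 ms
#' and tau = 20 steps, i.e. 20 ms PSPs and refractory windows.
#'
#' @param tau refractory/PSP length in steps.
#' @param dt step duration in ms.
#' @param nSweeps recorded sweeps.
#' @param burnIn discarded initial sweeps.
#' @param updateOrder "fixed" or "random".
#' @param mechanism "absolute" or "relative".
#' @param pspMode "rect" or "alpha".
#' @return A [SamplerConfig-class] object.
#' @export
samplerConfig <- function(tau = 20L, dt = 1, nSweeps = 10000L, burnIn = 1000L,
                          updateOrder = "fixed", mechanism = "absolute",
                          pspMode = "rect") {
  new("SamplerConfig", tau = as.integer(tau), dt = as.numeric(dt),
      nSweeps = as.integer(nSweeps), burnIn = as.integer(burnIn),
      updateOrder = updateOrder, mechanism = mechanism, pspMode = pspMode)
}

setMethod("show", "SamplerConfig", function(object) {
  cat(sprintf(
    "SamplerConfig: %s mechanism, tau = %d, dt = %g ms, %d sweeps (+%d burn-in), %s order, %s PSPs\n",
    object@mechanism, object@tau, object@dt, object@nSweeps, object@burnIn,
    object@updateOrder, object@pspMode))
})

#' Spike record
#'
#' Timestamped spikes and per-sweep binary state snapshots of a sampling run.
#'
#' @slot spikes data.frame with columns `time_ms` (nondecreasing) and
#'   `neuron` (1-based index).
#' @slot states integer matrix of recorded binary states, one row per
#'   snapshot, one column per neuron (may have zero rows).
#' @slot dt step duration in ms (NA for continuous-time records).
#' @slot tau refractory/PSP duration (steps for discrete, ms for continuous).
#' @slot K integer number of neurons.
#' @export
setClass("SpikeRecord",
         representation(spikes = "data.frame", states = "matrix",
                        dt = "numeric", tau = "numeric", K = "integer"))

setValidity("SpikeRecord", function(object) {
  sp <- object@spikes
  if (!all(c("time_ms", "neuron") %in% names(sp)))
    return("spikes must have columns time_ms and neuron")
  if (nrow(sp) > 1L && is.unsorted(sp$time_ms))
    return("spike times must be nondecreasing")
  if (nrow(sp) && (any(sp$neuron < 1L) || any(sp$neuron > object@K)))
    return("neuron indices out of range")
  if (ncol(object@states) != object@K && nrow(object@states) > 0L)
    return("state snapshots must have K columns")
  TRUE
})

setMethod("show", "SpikeRecord", function(object) {
  cat(sprintf("SpikeRecord: K = %d, %d spikes, %d state snapshots",
              object@K, nrow(object@spikes), nrow(object@states)))
  if (!is.na(object@dt)) cat(sprintf(", dt = %g ms", object@dt))
  cat(sprintf(", tau = %g\n", object@tau))
})

#' Postsynaptic potential kernel
#'
#' Either the rectangular renewal PSP of the exact theory (value 1 for tau
#' steps after a spike, renewed rather than summed on repeated firing), or
#' the biologically more realistic additive alpha-shaped kernel
#' \deqn{\epsilon(t) = \kappa (e^{-t/\tau_{fall}} - e^{-t/\tau_{rise}}),
#'  \quad t \ge 0,}
#' whose time integral \eqn{\kappa(\tau_{fall}-\tau_{rise})} is matched to
#' that of the rectangular pulse (tau * dt).
#'
#' @slot shape "rect" or "alpha".
#' @slot tauRise rise time constant in ms.
#' @slot tauFall fall time constant in ms.
#' @slot kappa scaling factor.
#' @slot tau duration of the rectangular reference pulse in ms.
#' @export
setClass("PSPKernel",
         representation(shape = "character", tauRise = "numeric",
                        tauFall = "numeric", kappa = "numeric",
                        tau = "numeric"))

setValidity("PSPKernel", function(object) {
  if (!object@shape %in% c("rect", "alpha"))
    return("shape must be 'rect' or 'alpha'")
  if (object@shape == "alpha" && object@tauRise >= object@tauFall)
    return("tauRise must be < tauFall")
  TRUE
})

#' Construct a PSP kernel
#'
#' Defaults reproduce the alpha-shaped PSP variant: fall time equal to the
#' PSP duration tau (20 ms), rise time 3 ms, and scaling
#' kappa = tau / (tauFall - tauRise) = 20/17, which matches the kernel's time
#' integral to that of the rectangular pulse.
#'
#' @param shape "rect" or "alpha".
#' @param tau duration of the rectangular reference pulse in ms.
#' @param tauRise rise time constant in ms (alpha shape).
#' @param tauFall fall time constant in ms (alpha shape); defaults to tau.
#' @param kappa scaling factor; defaults to the integral-matching value.
#' @return A [PSPKernel-class] object.
#' @export
pspKernel <- function(shape = c("alpha", "rect"), tau = 20, tauRise = 3,
                      tauFall = tau, kappa = tau / (tauFall - tauRise)) {
  shape <- match.arg(shape)
  if (shape == "rect") { tauRise <- 0; tauFall <- tau; kappa <- 1 }
  new("PSPKernel", shape = shape, tauRise = as.numeric(tauRise),
      tauFall = as.numeric(tauFall), kappa = as.numeric(kappa),
      tau = as.numeric(tau))
}

#' Evaluate a PSP kernel at given lags
#'
#' @param kernel a [PSPKernel-class] object.
#' @param t numeric vector of lags since the spike, in ms.
#' @return kernel values (0 for t < 0).
#' @export
evalKernel <- function(kernel, t) {
  out <- numeric(length(t))
  pos <- t >= 0
  if (kernel@shape == "rect") {
    out[pos & t < kernel@tau] <- 1
  } else {
    out[pos] <- kernel@kappa *
      (exp(-t[pos] / kernel@tauFall) - exp(-t[pos] / kernel@tauRise))
  }
  out
}

setMethod("show", "PSPKernel", function(object) {
  if (object@shape == "rect")
    cat(sprintf("PSPKernel: rectangular, duration %g ms\n", object@tau))
  else
    cat(sprintf(
      "PSPKernel: alpha, tauRise = %g ms, tauFall = %g ms, kappa = %.4g\n",
      object@tauRise, object@tauFall, object@kappa))
})

#' Orientation-tuned rivalry network
#'
#' Neurons on a centered hexagonal grid, each with a preferred orientation
#' and a periodic tuning curve; synapses exist only between neurons within a
#' grid-distance cutoff.  Boltzmann parameters are trained with contrastive
#' divergence.
#'
#' @slot coords n x 2 matrix of grid positions (unit nearest-neighbor
#'   spacing).
#' @slot phiHat preferred orientation per neuron in [0, pi).
#' @slot tuning list with elements `base`, `contrast`, `peak` (tuning-curve
#'   parameters shared by all neurons).
#' @slot params trained [BoltzmannParams-class].
#' @slot connectionRadius grid-distance cutoff for synapses.
#' @slot mask logical connectivity matrix (TRUE = synapse permitted).
#' @export
setClass("RivalryNetwork",
         representation(coords = "matrix", phiHat = "numeric",
                        tuning = "list", params = "BoltzmannParams",
                        connectionRadius = "numeric", mask = "matrix"))

setValidity("RivalryNetwork", function(object) {
  n <- nrow(object@coords)
  if (length(object@phiHat) != n) return("phiHat length must match grid size")
  if (nNeurons(object@params) != n) return("params dimension must match grid size")
  if (any(object@params@W[!object@mask] != 0))
    return("weights outside the connectivity mask must be zero")
  if (!isTRUE(all.equal(object@mask, t(object@mask))))
    return("connectivity mask must be symmetric")
  TRUE
})

setMethod("show", "RivalryNetwork", function(object) {
  cat(sprintf(
    "RivalryNetwork: %d neurons, connection radius %g, %d synapse pairs\n",
    nrow(object@coords), object@connectionRadius,
    sum(object@mask[upper.tri(object@mask)])))
})

#' Exhaustive sweep transition matrix for a small network
#'
#' The exact one-sweep transition matrix of the discrete-time sampler over
#' all (tau+1)^K refractory configurations, assembled as the ordered product
#' of the K per-neuron operator matrices.
#'
#' @slot matrix row-stochastic sparse transition matrix
#'   (\code{Matrix::dgCMatrix}).
#' @slot K integer number of neurons.
#' @slot tau integer refractory length.
#' @slot mechanism "absolute" or "relative".
#' @export
setClass("TransitionMatrixOracle",
         representation(matrix = "ANY", K = "integer", tau = "integer",
                        mechanism = "character"))

setMethod("show", "TransitionMatrixOracle", function(object) {
  cat(sprintf(
    "TransitionMatrixOracle: %s mechanism, K = %d, tau = %d, %d states\n",
    object@mechanism, object@K, object@tau, nrow(object@matrix)))
})
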