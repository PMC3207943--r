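---
title: "Sampling from Boltzmann distributions with spiking networks: models, solvers and design choices"
author: "NeuralSampling authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sampling from Boltzmann distributions with spiking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NeuralSampling)
```

## The model

The package treats the trajectory of binary activity states of a recurrent
network of stochastically spiking neurons as a Markov chain Monte Carlo
sampler.  The target is a Boltzmann distribution over $K$ binary variables,

$$p(v) = \frac{1}{Z}\exp\Big(\sum_k b_k v_k +
  \tfrac12 \sum_{k,j} W_{kj} v_k v_j\Big),
  \qquad W = W^\top,\; \operatorname{diag}(W) = 0,$$

where $W_{kj}$ plays the role of a synaptic weight and $b_k$ of a neuronal
excitability.  Variable $k$ is *active* ($v_k = 1$) while neuron $k$ is
within one PSP duration $\tau$ of its last spike.  This spike-based code is
bookkept by a per-neuron refractory variable $\zeta_k$: a spike sets
$\zeta_k = \tau$, it counts down by one per time step, and
$v_k = [\zeta_k > 0]$.

The link between the distribution and the dynamics is the *neural
computability condition*: the membrane potential of neuron $k$ must equal
the conditional log-odds of its variable,

$$u_k = \log\frac{p(v_k = 1 \mid v_{\setminus k})}
                  {p(v_k = 0 \mid v_{\setminus k})}
      = b_k + \sum_{j \neq k} W_{kj} v_j,$$

which for a Boltzmann target is exactly the usual linear drive with
rectangular PSPs of duration $\tau$.  `membranePotential()` implements it,
and the test suite verifies the log-odds identity against exact enumeration
on every state of small systems.

### Absolute refractory mechanism: exact sampling

The chain operates on the augmented state $(\zeta_1,\dots,\zeta_K)$.  Its
target is the joint distribution in which $\zeta_k \mid v_k{=}1$ is uniform
on $\{1,\dots,\tau\}$ and $\zeta_k = 0$ exactly when $v_k = 0$
(`jointAuxDistribution()`).  One sweep updates each neuron in turn: in the
resting state $\zeta_k = 0$ and in the last refractory state $\zeta_k = 1$
the neuron fires with probability $\sigma(u_k - \log\tau)$ ($\sigma$ the
logistic function; the $\log\tau$ offset compensates for the $\tau$ steps an
accepted spike keeps the variable active); deeper refractory states decay
deterministically.  This per-neuron operator leaves the augmented target
invariant, the sweep is irreducible and aperiodic, and the chain is
deliberately *irreversible* — detailed balance fails, which is what permits
temporally extended PSPs and refractoriness inside a valid sampler.

The package does not take these statements on faith: `buildTransitionMatrix()`
assembles the exact sweep operator of any small network as the ordered
product of per-neuron operator matrices, and `checkInvariance()` reports the
invariance residual, the eigenvalue-1 multiplicity, the stationary
distribution and the detailed-balance residual.  The acceptance suite runs
this verification over a grid of $(K, \tau)$ pairs with five random
parameter draws each; residuals sit at numerical zero ($<10^{-12}$) while
the detailed-balance residual is strictly positive.

### Relative refractory mechanism: locally correct sampling

Real neurons can fire again before their PSPs have decayed.  The relative
mechanism equips the neuron with a readiness profile $g(\zeta) \in [0, 1]$
($g(\tau) = 0$ just after a spike, $g(0) = 1$ at rest): from any state the
neuron re-fires with probability $g(\zeta_k)\, f(u_k)$ and otherwise
$\zeta_k$ decays by one.  The activation function $f$ is no longer the
logistic; it must solve, for every $u$,

$$f(u) \sum_{\zeta = 1}^{\tau} \;\prod_{i = 1}^{\zeta}
    \big(1 - g(i) f(u)\big)^{-1} \;=\; e^{u}.$$

This is the stationarity condition of the single-neuron chain: with $f$
chosen this way, a neuron receiving constant input $u$ has stationary
$P(v = 1) = \sigma(u)$ exactly, so each neuron's *local* computation is
correct even though the network's joint stationary distribution is only an
approximation to the target.  The left-hand side is continuous and strictly
increasing in $f$ on $(0, 1/\max_\zeta g(\zeta))$ with limits $0$ and
$\infty$, so the root is unique and bisection is globally safe
(`solveActivation()`).  Two desk-scale checks pin the transcription of this
equation: for the absolute profile ($g(1) = 1$, zero elsewhere) the solution
collapses analytically to $\sigma(u - \log\tau)$, and the enumerated
single-neuron chain for every shipped profile reproduces $\sigma(u)$ to
$10^{-6}$ across $u \in [-4, 4]$.

Because the resting-state firing probability is $f(u)$ itself, profiles must
recover full readiness ($\max g = 1$) for $f$ to remain a probability over
the whole potential range; the solver rejects profiles that do not, with an
explicit error.  The shipped profiles are power-law recoveries
$g(\zeta) = ((\tau - \zeta)/(\tau - 1))^p$ with $p = 0.5$ ("early"), $2$
("moderate") and $8$ ("late", close to an absolute mechanism); arbitrary
tables, including non-monotonic ones that model preferred interspike
intervals, are accepted via `makeProfile("table", ...)`.

### Continuous time

The discrete chain has a well-defined $\Delta t \to 0$ limit: a Markov jump
process in which $\zeta_k$ decays linearly, recoveries are deterministic
events $\tau$ ms after each spike, and a resting neuron fires with rate
$e^{u_k}/\tau$ — the rate whose renewal process has active-time fraction
$r\tau/(1 + r\tau) = \sigma(u_k)$.  `runJumpProcess()` simulates this
process exactly by event-driven competition of exponential clocks (rates are
piecewise constant between events, so no discretisation error is incurred),
and `discretizationConsistency()` shows the discrete chain's divergence
approaching the continuous chain's as $\Delta t$ shrinks.  For relative
mechanisms in continuous time the package provides the matched rate
function (`solveActivationContinuous()`, solving
$f\int_0^\tau \exp(f\int_0^x g)\,dx = e^u$); event-driven simulation of that
state-dependent-rate process would require thinning and is deliberately out
of scope.

### Alpha-shaped additive PSPs

The exact theory uses rectangular *renewal* PSPs (a re-fired neuron prolongs
its partner's depolarisation rather than adding to it).  As a realism
variant, `pspMode = "alpha"` computes membrane potentials by convolving each
presynaptic spike train with the kernel
$\epsilon(t) = \kappa\,(e^{-t/\tau_{fall}} - e^{-t/\tau_{rise}})$, PSPs
summing additively.  Defaults: $\tau_{fall} = \tau = 20$ ms,
$\tau_{rise} = 3$ ms, and $\kappa = \tau/(\tau_{fall} - \tau_{rise}) = 20/17$
so that the kernel's time integral equals that of the rectangular pulse.
The sampled binary state remains defined by the refractory variables; only
the drive changes.  This variant is an approximation and is evaluated as
such (its divergence is visibly larger than the renewal case but far below
the factorised baseline).

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| $\tau$ | 20 | steps | PSP/refractory duration; with $\Delta t = 1$ ms this is a 20 ms PSP, and the firing offset $\log\tau$ keeps activity calibrated |
| $\Delta t$ | 1 | ms | biological duration of one MCMC sweep |
| burn-in | 1000 | sweeps | discarded initialisation transient (one second) |
| update order | fixed ascending |  | per-sweep sequential scan; a fresh random permutation per sweep is available and equally valid |
| Laplace pseudo-count | 1 |  | added to every state tally before computing divergences |
| ensemble bias prior | $\mathcal N(-1.5, 0.5^2)$ |  | keeps random targets in a sparse-activity regime; configurable |

## What the synthetic generators emulate

`randomBoltzmann()` draws the study's random target ensembles: off-diagonal
weights i.i.d. $\mathcal N(0, \sigma_W^2)$ symmetrised with zero diagonal,
biases from the Gaussian prior above.  $\sigma_W \in \{0.03, 0.3, 3.0\}$
spans near-independent, moderately dependent, and strongly concentrated
targets (at $\sigma_W = 3$ the median target carries 90% of its mass on
fewer than ten of the 1024 states at $K = 10$).  These are abstract
parameter ensembles, not fits to biological connectivity; passing tests
demonstrate correctness of the sampling machinery on such targets, not that
cortical networks implement these exact weights.

The rivalry generator emulates a minimal orientation-selective population:
neurons on a centered hexagonal grid (5 layers / 91 neurons by default;
8 layers / 217 for the full-scale run), preferred orientations equally
spaced on $[0, \pi)$ and randomly assigned to sites, and a $\pi$-periodic
tuning curve $tc(\phi) = a + c\,e^{p(\cos 2(\phi - \hat\phi) - 1)}$ clipped
to $[0,1]$.  Training patterns activate each neuron independently with
probability $tc(\phi)$ at a uniformly drawn global orientation — a
fully-visible Boltzmann-machine training signal, not a model of retinal
input.

## Numerical choices

* **Activation solver.** Grid $[-10, 10]$ in steps of $0.01$ (the logistic
  saturates to within $5\times10^{-5}$ at the ends), 64 bisection halvings
  per node (machine-precision roots), piecewise-constant nearest-node
  lookup, out-of-range potentials clipped with a warning.
* **Continuous solver.** The inner integrand $e^{fG(x)}$ spans many orders
  of magnitude, which defeats adaptive quadrature's error heuristics;
  composite Simpson on a fixed 2001-node grid of the cached cumulative
  readiness integral is used instead, with `uniroot` on a doubling bracket.
* **Stationary distributions.** Dense left-eigendecomposition up to 4000
  states, power iteration (tolerance $10^{-13}$) beyond; eigenvalue-1
  multiplicity counted as $|\lambda - 1| < 10^{-9}$.
* **Clamping.** Observed neurons are frozen ($\zeta = \tau$ for observed 1,
  $\zeta = 0$ for observed 0) and skipped by the sweep, so the free neurons
  sample the exact conditional; this was chosen over strong-current
  injection because it makes the conditional target exact rather than
  approximate.
* **State coding.** Binary states are coded as integers with neuron 1 as
  the least-significant bit; refractory configurations as base-$(\tau+1)$
  integers with neuron 1 varying fastest.  A single fixed convention makes
  oracle comparisons bit-exact.
* **Initialisation.** Chains start all-resting; the one-second burn-in
  is ample for every system size used here.
* **RNG.** All simulators consume R's RNG (one uniform per neuron update,
  in sweep order), so `set.seed()` reproduces entire trajectories bitwise,
  including the C++ cores.
* **Gamma fitting.** Maximum likelihood via the profile-likelihood
  reduction: the ML scale given shape is $\bar x / k$, and the remaining
  shape equation $\log k - \psi(k) = \log\bar x - \overline{\log x}$ is
  strictly monotone, solved by bracketed root search to $10^{-8}$.

## Evaluating samplers against the finite-sample floor

Divergences are Laplace-smoothed KL divergences (natural log) between the
exact enumerated target and the empirical state distribution.  An exact
sampler does not reach zero at finite $N$; `noiseFloorKL()` measures the
divergence i.i.d. draws from the target itself would show.  Successive
per-sweep snapshots of any refractory chain are correlated on the timescale
of $\tau$, so their divergence sits a factor of order $\tau$ above the
i.i.d. floor without indicating any systematic error.  The package
therefore compares against the floor using snapshots thinned beyond one
renewal window (spacing $2\tau$), where the chain is statistically
indistinguishable from i.i.d. sampling, and the ensemble comparison records
its $10^5$ samples with spacing $\tau$ for the same reason.  Ensemble KL
spreads are summarised on the log scale: across random strongly-coupled
targets the factorised baseline's divergence is extremely right-skewed, and
the meaningful statement — the factorised error exceeds the relative
mechanism's by 1–2 orders of magnitude — is a log-scale one.

## Rivalry demonstration: calibration of figure-level knobs

The perceptual-multistability pipeline reproduces a phenomenology, not a
quantity: trained connectivity excitatory between similar preferred
orientations and inhibitory between dissimilar ones; free-running
("prior") activity that visits coherent percepts of arbitrary orientation;
an eight-neuron ambiguous clamp (two neurons near each of the two orthogonal
stimulus orientations held active, two near each intermediate orientation
$\pi/4,\,3\pi/4$ muted — the directions orthogonal to the stimuli in the
doubled-angle population-vector plane) that yields a bimodal posterior with
stochastic switching; and Gamma-distributed dominance durations.

Several constants here are genuinely open design choices, fixed as follows
at the 91-neuron development scale and exposed as configuration: connection
radius 4 grid units (smaller radii leave the clamp's influence too local to
carve two modes out of the rotationally symmetric prior), tuning base
sensitivity 0.03, contrast 0.8, peakedness 2 (broad, V1-like curves —
sharper curves decorrelate moderately-similar pairs and destroy the
excitatory/inhibitory weight structure), $2\times10^4$ contrastive-divergence
patterns with 50 decorrelation sweeps and learning rate 0.01.
Population-vector decoding uses the generative preferred orientations; the
doubled-angle convention makes orthogonal orientations cancel.  Percept
regions for switch detection are sectors of half-width $\pi/8$ around the
two doubled stimulus directions with a magnitude threshold of 25% of the
95th-percentile prior magnitude; a switch requires entering the opposite
percept region, so neutral-region excursions never count (hysteresis).
Because a single run dwells asymmetrically in the two percepts, bimodality
is judged by the mean occupancy of the two mode sectors against
equal-width intermediate sectors, together with a minimum switch count.

An option to re-measure preferred orientations from network responses
before decoding (fitting tuning curves to clamped-stimulation trials) was
considered and omitted: the generative and measured orientations agree
closely in this regime, and the generative ones keep the demonstration
deterministic given the seed.

## Problem sizes

The default test and verification runs use: exhaustive operator
verification up to $(\tau + 1)^K = 125$ joint states; $10^6$-sweep discrete
runs at $K = 5$; $10^6$ ms continuous runs at $K \le 3$; ensembles of 20
random targets per weight scale at $K = 10$ with $10^5$ recorded samples
each; and the 91-neuron rivalry network with 60 s of simulated activity.
These sizes were chosen so the full verification completes in minutes on a
single core while every statistical band (3 standard errors, noise-floor
comparisons) retains its meaning; the full-scale 217-neuron rivalry run and
larger ensembles are available through the same functions by changing the
corresponding arguments.

## Known limitations

* The relative mechanism is *locally* correct only; its global stationary
  distribution deviates from the target (quantified, small).  This is a
  property of the model, not a bug.
* Alpha-PSP sampling has no invariance guarantee at all; it is evaluated
  empirically.
* The continuous-time engine implements the absolute mechanism only.
* Membrane dynamics are abstract (no leak, conductances, or adaptation);
  PSPs are symbolic step or alpha kernels.
* The rivalry model clamps binary observations directly and has no stimulus
  front-end or contrast variable; dominance-duration statistics at the
  91-neuron scale are qualitative.
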