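# NeuralSampling

Markov chain Monte Carlo sampling from Boltzmann distributions over binary
variables, implemented by the dynamics of a network of stochastically
spiking neurons.

## The problem

Probabilistic inference by sampling is a leading hypothesis for how cortical
networks handle uncertainty, but standard samplers for distributions over
binary variables (Gibbs sampling / Glauber dynamics) are *reversible* chains
with instantaneous state flips — incompatible with two basic features of
spiking neurons: a spike affects its targets for a finite postsynaptic
potential (PSP) duration, and a neuron that just fired is refractory.  This
package implements a family of **irreversible** samplers in which those two
features are not obstacles but the mechanism itself.

Each neuron `k` carries a refractory countdown `ζ_k`; a spike sets
`ζ_k = τ` and the binary variable it codes is active, `v_k = 1`, while
`ζ_k > 0` (a rectangular PSP of `τ` time steps).  For a Boltzmann target

    p(v) ∝ exp( Σ_k b_k v_k + ½ Σ_{k,j} W_kj v_k v_j ),
    W symmetric, zero diagonal,

the membrane potential `u_k = b_k + Σ_j W_kj v_j` equals the conditional
log-odds of `v_k` (the *neural computability condition*), and:

* **Absolute refractory mechanism** — firing with probability
  `σ(u_k − log τ)` from the resting and last refractory states, with
  deterministic countdown in between, leaves an augmented target over
  `(v, ζ)` *exactly* invariant: the spiking network is an exact, irreversible
  MCMC sampler of `p(v)`.  Verified here by exhaustive transition-matrix
  enumeration, not assumed.
* **Relative refractory mechanism** — a readiness profile `g(ζ)` allows
  early re-firing; the matching activation function `f(u)` solves
  `f Σ_ζ Π_{i≤ζ} (1 − g(i) f)⁻¹ = e^u` and makes every *single-neuron*
  conditional exact ("locally correct" sampling); the network distribution
  becomes a close approximation, orders of magnitude better than a
  factorised model.
* **Continuous time** — the `Δt → 0` limit is a Markov jump process
  (resting neurons fire at rate `e^u/τ`), simulated exactly by event-driven
  competition of exponential clocks.
* **Inference by clamping** — freezing observed neurons makes the free
  neurons sample the exact conditional distribution; a 91/217-neuron
  orientation-tuned network trained with contrastive divergence demonstrates
  perceptual rivalry: a bimodal posterior under an ambiguous stimulus, with
  Gamma-distributed dominance durations.

Intended users: computational neuroscientists studying sampling-based
cortical computation, and anyone needing a verified irreversible sampler
for small Boltzmann systems with exhaustive ground-truth oracles.

## Worked example

```r
library(NeuralSampling)

## a random 5-neuron target
params <- randomBoltzmann(K = 5, sigmaW = 0.5, seed = 42)
params
#> BoltzmannParams over 5 binary variables
#>   weights: sd 0.418, range [-0.282, 1.01]
#>   biases : mean -1.32, range [-2.19, -0.357]
exact <- exactDistribution(params)

## exhaustive verification of exact invariance (and irreversibility)
orc <- buildTransitionMatrix(params, tau = 3)
chk <- checkInvariance(orc, jointAuxDistribution(params, tau = 3))
chk$invariance_residual        #> 2.78e-17  (the augmented target is invariant)
chk$eig1_multiplicity          #> 1         (unique stationary distribution)
chk$detailed_balance_residual  #> 0.03      (> 0: the chain is irreversible)

## one million sweeps of the spiking sampler
cfg <- samplerConfig(tau = 20, nSweeps = 1e6, burnIn = 1000)
rec <- runChain(params, cfg, seed = 1, recordStates = FALSE,
                countStates = TRUE)
emp <- empiricalDistribution(attr(rec, "counts"), K = 5)
klDivergence(exact, emp)                        #> 0.000133
klDivergence(exact, factorizedApprox(exact))    #> 0.0421
mean(noiseFloorKL(exact, n = 1e6, seed = 2))    #> 1.67e-05
```

The sampler's divergence (1.3e-4) sits at the finite-sample scale — two
orders of magnitude below the error of a factorised model with correct
marginals (0.042) and within the snapshot-autocorrelation factor of the
i.i.d. floor (1.7e-5).  The biologically richer relative mechanism is just
as close on this target:

```r
g <- makeProfile("moderate", tau = 20)   # readiness recovers as a power law
f <- solveActivation(g)                  # activation matched to g
cfgR <- samplerConfig(tau = 20, nSweeps = 1e6, burnIn = 1000,
                      mechanism = "relative")
recR <- runChain(params, cfgR, g = g, f = f, seed = 3,
                 recordStates = FALSE, countStates = TRUE)
klDivergence(exact, empiricalDistribution(attr(recR, "counts"), 5))
#> 0.000132
```

Other entry points: `runJumpProcess()` (continuous time),
`gibbsChain()` (reference sampler), `ensembleExperiment()` (mechanism
comparison across random target ensembles), `firingStatistics()` (ISIs, CV,
rates), and `buildGrid()` / `cdTrain()` / `runRivalryExperiment()` (the
rivalry demonstration).  A thin command-line wrapper ships as
`inst/scripts/neural-sampling` with subcommands `sample`, `sample-ct`,
`solve-activation`, `evaluate`, `oracle-check` and `rivalry`.

See the methods vignette (`vignettes/neural-sampling-methods.Rmd`) for the
model, solver details and design choices.

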