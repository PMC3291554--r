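---
title: "Self-organising state-space smoothing for conductance-based neuron models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-organising state-space smoothing for conductance-based neuron models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sossm)
```

## The estimation problem

A conductance-based neuron model describes the membrane potential of one or
more isopotential compartments through current conservation,

$$C_m \frac{dV}{dt} = I_{inj}(t) - g_L (V - E_L) - \sum_i \bar g_i\,
x_i^{p_i} y_i^{q_i} (V - E_i),$$

with gating variables relaxing towards voltage-dependent steady states,
$\dot x = (x_\infty(V) - x)/\tau_x(V)$.  Fitting such a model to a
current-clamp recording is hard because almost everything is hidden: only a
noisy voltage trace is observed, while the gates, the calcium concentrations
and all biophysical parameters (maximal conductances, reversal potentials,
kinetics, noise levels) are not.

This package treats the problem as inference in a stochastic state-space
model.  The dynamics are integrated with the Euler–Maruyama scheme at step
$\delta$, with intrinsic (diffusion) noise of standard deviation
$\sigma_{sys}\sqrt{\delta}$ entering the voltage equations, and observations
are voltage samples corrupted by Gaussian noise of standard deviation
$\sigma_{obs}$, taken every $k$ integration steps.  A bootstrap particle
filter — the proposal is the transition density, so importance weights reduce
to the observation likelihood — is extended in two ways:

1. **Fixed-lag smoothing.**  Each particle stores its trajectory over the
   last $L$ observation steps, and resampling (systematic, triggered when the
   effective sample size drops below half the ensemble) replaces whole
   lag-window trajectories.  The weighted ensemble at offset $L$ then
   approximates the smoother density $p(x_{t-L} \mid y_{1:t})$.

2. **Self-organisation.**  The state is extended with the unknown parameter
   vector $\theta$ and a per-particle scale factor $\tau$.  At every
   observation step, each particle's parameters are resampled from an
   adaptive multivariate normal proposal
   $\theta_i \sim N(m_i, \tau_i^2 C)$ where, with ensemble weighted mean
   $E[\theta]$ and covariance $\mathrm{Cov}[\theta]$:
   $m_i = \theta_i + a\,(E[\theta] - \theta_i)$ (per particle),
   $C \leftarrow (1-b)\,C + b\,\mathrm{Cov}[\theta]$ (shared), and
   $\tau_i \leftarrow \tau_i e^{c\xi}$ with $\xi \sim N(0,1)$ (log-normal,
   per particle), clamped to a prior interval.  The order matters and is
   fixed: moments, then $\tau$, then $m$, then $C$, then $\theta$, then the
   hidden states conditioned on the new $\theta$.  Selection acts only
   through the subsequent weighting and resampling, so good parameter values
   — and the scale factors that generated them — are multiplied: an
   evolution-strategy mechanism (covariance matrix adaptation with
   log-normal step-size control) embedded in a particle smoother.

With the adaptation switched off ($a = b = c = 0$, fixed $\tau$) the
proposal degenerates to a plain Gaussian random walk on $\theta$; the
adaptation's practical effect is a large reduction in the variance of the
parameter estimates, which the test suite demonstrates on conductance
recovery tasks.

Parameters are confined to a prior box by componentwise clamping; the
initial ensemble is sampled uniformly from that box.  Weights are handled in
the log domain with max subtraction, and a run in which every weight
underflows is reported as a degenerate-ensemble error rather than silently
reset.

## Model families and their coefficients

Three families ship with the package (`buildModel`):

* `hh1c` — one compartment with transient sodium ($m^3 h$) and
  delayed-rectifier potassium ($n^4$) currents plus leak.  Conductances,
  reversal potentials and sigmoid kinetics follow the classic squid-axon
  description (resting potential near $-60$ mV, $\bar g_{Na} = 120$,
  $\bar g_K = 36$, $g_L = 0.3$ mS/cm²).  Its registry flags exactly 23
  estimable parameters: 3 conductances, 3 reversal potentials, 15 kinetic
  coefficients (per gate: half-activation voltage, slope, and the base,
  amplitude and width of the relaxation-time curve) and the two noise SDs.
* `motoneuron2c` — a two-compartment (soma + dendrite) vertebrate
  motoneuron in the tradition of reduced cat spinal-motoneuron models:
  sodium (instantaneous $m_\infty^3 h$ activation) and delayed-rectifier
  potassium at the soma; N-type calcium and calcium-activated potassium in
  both compartments; L-type calcium in the dendrite only; first-order
  calcium pools in both; coupling conductance $g_c$ scaled by the soma area
  ratio $\rho$, with injected current likewise scaled per compartment.
* `b4` — a single-compartment snail (*Lymnaea*) B4-type motoneuron: leak,
  transient sodium with instantaneous activation, delayed-rectifier
  potassium and an A-type potassium current, all with constant relaxation
  times; 17 estimable parameters.

Steady states use one logistic family for activation and inactivation alike
(inactivation is simply a negative slope).  Voltage-dependent relaxation
times use a symmetric bell,
$\tau(V) = \tau_0 + A/\cosh((V - V_c)/w)$, which is positive everywhere,
peaks at $\tau_0 + A$ at its center and decays to the base level away from
it; constant relaxation times are the $A = 0$ special case.  The exact
functional form of published relaxation-time fits varies across the
literature; the bell above was chosen because it has the fewest coefficients
with the required shape (base, amplitude, center, width), and the `hh1c`
coefficients were fitted by eye to the classic squid-axon curves
($\tau_h$ peaking near 8.6 ms at $-62$ mV, $\tau_n$ near 5.8 ms, $\tau_m$
below 0.5 ms).  The motoneuron and B4 coefficient sets are adapted from the
respective modelling literatures and calibrated so that the default models
are excitable under the default stimulation protocols (the B4 cell fires
repetitively above roughly 2 nA); since the original B4 recordings are not
public, the B4 family here is a synthetic study target, not a fitted model
of a particular cell.

The registry (`paramRegistry`) is the single source of truth at evaluation
time: every parameter has a unit, default, prior interval and free/fixed
flag, and some kinetic parameters carry an additional *narrow* prior
(`narrowBounds`) used in informative-prior experiments.  Models serialise to
YAML (`writeModelConfig`) with 17-digit numbers so a round trip reproduces
drift evaluations bit for bit; unknown keys are rejected on read.

## The synthetic-data generator

`generateProtocol` draws a random current-step protocol — i.i.d. uniform
amplitudes and durations, the last step truncated — and `simulateRecording`
integrates the stochastic model and adds observation noise.  Defaults:
integration step $\delta = 0.02$ ms with $k = 5$ substeps per sample
(0.1 ms sampling), chosen so that spikes are resolved and the Euler–Maruyama
discretisation error is far below the observation noise (the test suite
verifies monotone convergence towards a high-order reference solution as
$\delta$ halves, a sub-millivolt pointwise bound on subthreshold responses
at $\delta = 0.01$ ms, and spike-time agreement within 0.5 ms).  A pointwise
voltage bound is quantified on *subthreshold* responses deliberately: on the
steep flank of an action potential (several hundred mV/ms) any integrator's
tiny phase error translates into a large instantaneous voltage difference,
so spike-regime accuracy is assessed through spike counts and timing
instead.

For the single-compartment recovery studies the default protocol spans
$-5$ to $20$ µA/cm² with 10–100 ms steps over 2 s, producing a mixture of
quiescence, subthreshold responses and repetitive firing.  Intrinsic noise
defaults to $\sigma_{sys} = 0.5$ mV·ms$^{-1/2}$ on the voltage equations
only (gate noise is available but defaults to zero, matching the
large-channel-number assumption) and $\sigma_{obs} = 1$ mV observation
noise, with 5 mV used as the "very noisy" regime.  What the generator does
*not* emulate: electrode artifacts, slow drift, temperature effects,
channel-noise discreteness, or morphology beyond two compartments — so
passing recovery tests demonstrates correctness of the inference machinery
under the model's own assumptions, not robustness to real-data
mis-specification.

## Numerical choices

* Gates are clipped to $[0,1]$ and calcium floored at 0 after every
  Euler–Maruyama substep; a voltage magnitude above 500 mV aborts the
  simulator (and kills the offending particle inside the smoother, where
  wild parameter proposals can transiently destabilise the dynamics).
* The proposal covariance receives a jitter of $10^{-12}$ times its mean
  diagonal (floored at $10^{-300}$) before Cholesky factorisation; the
  ensemble covariance can collapse to numerical zero late in a run and must
  stay factorisable.
* The smoother's hot loop uses a dedicated xoshiro256++ generator with polar
  normal variates, seeded from R's RNG, so `set.seed` still governs every
  draw and identical seeds replay bit-identically.
* Smoothed estimates for the first $L$ observations are backfilled from the
  buffer once it first fills (and the final $L$ from the terminal buffer),
  so smoothed traces cover the full recording.
* The "final estimate" of a run is the mean of the posterior-mean chain over
  the trailing 20% of observation times (configurable), and the associated
  SD over the same window is the variance diagnostic used in the adaptation
  and scale-floor comparisons.

## Default settings and what they mean

| setting | default | meaning |
|---|---|---|
| `nParticles` | 1000–2000 | ensemble size; recovery studies use 2000 |
| `lag` | 100 | smoothing lag in observation steps (10 ms at 0.1 ms sampling) |
| `resampleThreshold` | 0.5 | resample when ESS < 0.5 N |
| `adaptA`, `adaptB`, `adaptC` | 0.1 | adaptation rates of proposal mean, covariance, scale |
| `tauInterval` | [0, 0.5] | prior interval of the scale factor; a zero floor lets estimates collapse to a point, a positive floor preserves posterior spread |
| `jitter` | 1e-12 | relative covariance jitter |

The scale-factor interval is the practical dial between "point estimate"
and "posterior approximation": with $\tau_{lo} = 0$ resampling drives
$\tau$ towards zero and the parameter cloud contracts onto a near-point
estimate close to the truth; with a positive floor the cloud keeps
fluctuating and its spread approximates posterior uncertainty.  Both modes
are exercised in the tests.

## Multi-trace fitting

`fitMultiTrace` carries one hidden-state block per recording inside each
particle while sharing a single $\theta$ and $\tau$; the observation weight
is the product over traces.  This matters for sparse recordings: during a
long silent stretch the likelihood carries no information about the
conductances and the parameter random walk drifts.  When several traces are
active in complementary epochs, the joint fit always has an informative
channel.  The acceptance suite builds four B4-style traces, each active in a
different quarter of the run, and verifies that the joint fit's terminal
estimate spread does not exceed that of the best single-trace fit.

## Desk-scale study sizes

The bundled experiments are sized for a desktop single-core run: recovery
studies use 0.5–2 s of simulated data at 0.1 ms sampling with 500–2000
particles, and the replicate counts are 2–10.  These sizes reproduce the
qualitative phenomena reliably (variance reduction by adaptation, the
scale-floor effect, noise-dependent dispersion, the fixed-lag benefit,
multi-trace gains) and give conductance recovery within 10% in most
replicates.  Full-size joint estimation of all 23 (or, for the
two-compartment model, 31) parameters over long recordings is exposed
through the same API — `runScenario` with `narrowBounds` priors — but takes
hours, and identifiability then depends strongly on informative priors: the
high-dimensional runs in the test suite only assert property-level criteria
(estimates inside the prior box, smoothed-voltage RMSE below twice the
observation noise, a contracting proposal covariance).

## Known limitations

* The proposal is the transition density; very low observation noise makes
  weights peaky and forces resampling nearly every step.  Below roughly
  0.5 mV observation noise at 0.1 ms sampling the effective sample size
  collapses to one at every spike flank, and particle impoverishment — not
  the data — then dominates the run-to-run dispersion of the estimates.
  Auxiliary or lookahead proposals would mitigate this but are out of
  scope.
* Because of the same mechanism, the expected *monotone* growth of
  estimate dispersion with observation noise is hard to demonstrate at desk
  scale: at the low end impoverishment inflates dispersion, and for
  parameters whose true value happens to lie near the centre of the prior
  box (as `g_na` does in `hh1c`) the burn-in attraction towards the
  ensemble mean masks the degradation at the high end.  The corresponding
  check in the test suite documents this as a known failure rather than
  relaxing the comparison; the degradation is visible instead in the drift
  of `g_k` and `sigma_sys` towards their prior centres as noise grows.
* Artificial parameter evolution injects extra variance into the dynamics;
  its practical signature is a modest upward bias in the estimated
  intrinsic-noise SD while parameters are still moving.
* The noise-SD estimates ($\sigma_{sys}$ especially) are weakly identified
  from a single short trace and absorb discretisation and adaptation
  artifacts; conductances and reversal potentials are the robustly
  recovered quantities at desk scale.
* Componentwise clamping places point mass on the prior bounds; the
  per-parameter bound-hit counts in `FitResult` make this visible.
* A worked example:

```{r example, eval = FALSE}
m   <- buildModel("hh1c")
pro <- generateProtocol(-5, 20, 10, 100, totalT = 2000, seed = 1)
rec <- simulateRecording(m, pro, noiseSpec(sigmaSys = 0.5, sigmaObs = 1),
                         seed = 1)
fit <- runFixedLagSmoother(m, rec, c("sigma_sys", "sigma_obs", "g_na", "g_k"),
                           smootherConfig(nParticles = 2000, lag = 100,
                                          seed = 2))
finalEstimate(fit)
```
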