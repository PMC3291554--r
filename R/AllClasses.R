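#' @import methods
NULL

#' Voltage-dependent gating kinetics
#'
#' First-order gate kinetics in the Hodgkin-Huxley formalism: the steady state
#' is a logistic sigmoid of voltage, \eqn{x_\infty(V) = 1/(1 + \exp(-(V -
#' V_{1/2})/s))}, and the relaxation time is either a constant or a symmetric
#' bell-shaped function of voltage, \eqn{\tau(V) = \tau_0 + A /
#' \cosh((V - V_c)/w)}.  A positive slope gives an activation-like
#' (monotonically increasing) steady state, a negative slope an
#' inactivation-like one; both use the same functional family.
#'
#' @slot name gate label, e.g. \code{"m"}.
#' @slot vHalf half-activation voltage (mV).
#' @slot slope sigmoid slope factor (mV, signed, nonzero).
#' @slot tauMode \code{"constant"} or \code{"voltage_dependent"}.
#' @slot tauConst relaxation time (ms) when constant.
#' @slot tauParams named numeric of length 4 (\code{base}, \code{amplitude},
#'   \code{center}, \code{width}) for the voltage-dependent bell: base level
#'   and amplitude in ms, center and width in mV.
#'
#' @export
setClass("GateKinetics",
  representation(name = "character", vHalf = "numeric", slope = "numeric",
                 tauMode = "character", tauConst = "numeric",
                 tauParams = "numeric"),
  prototype(tauMode = "constant", tauConst = 1,
            tauParams = c(base = 1, amplitude = 0, center = 0, width = 10)))

setValidity("GateKinetics", function(object) {
  msg <- character()
  if (length(object@slope) != 1 || object@slope == 0 ||
      !is.finite(object@slope))
    msg <- c(msg, "slope must be a single nonzero finite number")
  if (!object@tauMode %in% c("constant", "voltage_dependent"))
    msg <- c(msg, "tauMode must be 'constant' or 'voltage_dependent'")
  if (object@tauMode == "constant") {
    if (object@tauConst <= 0)
      msg <- c(msg, "tauConst must be strictly positive")
  } else {
    tp <- object@tauParams
    if (length(tp) != 4)
      msg <- c(msg, "tauParams must have length 4 (base, amplitude, center, width)")
    else {
      vv <- seq(-120, 60, by = 1)
      tt <- tp[1] + tp[2] / cosh((vv - tp[3]) / tp[4])
      if (any(tt <= 0))
        msg <- c(msg, "relaxation time must be strictly positive on [-120, 60] mV")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Ionic-current specification
#'
#' A transmembrane current \eqn{I = \bar g \, x^p \, y^q \, (V - E)} with
#' optional activation gate \eqn{x} (dynamic or instantaneous), optional
#' inactivation gate \eqn{y}, and an optional calcium-dependence factor
#' \eqn{[\mathrm{Ca}]/([\mathrm{Ca}] + K_d)} for calcium-activated
#' conductances.  Passive (leak-like) currents have no gates.
#'
#' @slot name current label, e.g. \code{"na"}; used to derive the registry
#'   parameter names \code{g_<name>}.
#' @slot eRevName registry name of the reversal potential (shared between
#'   currents carried by the same ion, e.g. \code{"e_k"}).
#' @slot gMax maximal conductance (model unit system), nonnegative.
#' @slot eRev reversal potential default (mV).
#' @slot actGate \code{GateKinetics} or \code{NULL}.
#' @slot actPower integer in 1..4.
#' @slot inactGate \code{GateKinetics} or \code{NULL}.
#' @slot inactPower integer in 1..4.
#' @slot actMode \code{"dynamic"} or \code{"instantaneous"}.
#' @slot caModulation half-saturation constant \eqn{K_d} (concentration
#'   units) or \code{NA} when the current is not calcium-activated.
#' @slot carriesCalcium logical; \code{TRUE} for calcium currents feeding the
#'   compartment's calcium pool.
#'
#' @export
setClass("IonCurrentSpec",
  representation(name = "character", eRevName = "character", gMax = "numeric",
                 eRev = "numeric", actGate = "ANY", actPower = "integer",
                 inactGate = "ANY", inactPower = "integer",
                 actMode = "character", caModulation = "numeric",
                 carriesCalcium = "logical"),
  prototype(actGate = NULL, actPower = 1L, inactGate = NULL, inactPower = 1L,
            actMode = "dynamic", caModulation = NA_real_,
            carriesCalcium = FALSE))

setValidity("IonCurrentSpec", function(object) {
  msg <- character()
  if (object@gMax < 0) msg <- c(msg, "gMax must be nonnegative")
  if (object@actPower < 1L || object@actPower > 4L)
    msg <- c(msg, "actPower must be an integer between 1 and 4")
  if (object@inactPower < 1L || object@inactPower > 4L)
    msg <- c(msg, "inactPower must be an integer between 1 and 4")
  if (!is.na(object@caModulation) && object@caModulation <= 0)
    msg <- c(msg, "caModulation (Kd) must be positive when present")
  if (!object@actMode %in% c("dynamic", "instantaneous"))
    msg <- c(msg, "actMode must be 'dynamic' or 'instantaneous'")
  if (!is.null(object@actGate) && !is(object@actGate, "GateKinetics"))
    msg <- c(msg, "actGate must be a GateKinetics or NULL")
  if (!is.null(object@inactGate) && !is(object@inactGate, "GateKinetics"))
    msg <- c(msg, "inactGate must be a GateKinetics or NULL")
  if (length(msg)) msg else TRUE
})

#' Compartment specification
#'
#' One isopotential compartment: membrane capacitance, a leak current, a set
#' of gated ionic currents, and optionally a first-order intracellular
#' calcium pool \eqn{d[\mathrm{Ca}]/dt = -\alpha \sum I_{Ca} - k\,
#' [\mathrm{Ca}]}.
#'
#' @slot name compartment label (\code{"soma"}, \code{"dend"}).
#' @slot cM membrane capacitance (positive).
#' @slot gLeak leak conductance.
#' @slot eLeak leak reversal potential (mV).
#' @slot currents list of \code{IonCurrentSpec}.
#' @slot hasCalcium logical.
#' @slot caParams named numeric \code{c(alpha=, removal=)}: calcium influx
#'   scaling per unit calcium current and removal rate (1/ms), both positive.
#'
#' @export
setClass("CompartmentSpec",
  representation(name = "character", cM = "numeric", gLeak = "numeric",
                 eLeak = "numeric", currents = "list",
                 hasCalcium = "logical", caParams = "numeric"),
  prototype(hasCalcium = FALSE, caParams = c(alpha = 0, removal = 1)))

setValidity("CompartmentSpec", function(object) {
  msg <- character()
  if (object@cM <= 0) msg <- c(msg, "cM must be positive")
  if (object@hasCalcium && object@caParams[["removal"]] <= 0)
    msg <- c(msg, "calcium removal rate must be positive")
  if (length(msg)) msg else TRUE
})

#' Conductance-based neuron model
#'
#' A declarative model: an ordered list of compartments (one or two; two
#' compartments are coupled through a conductance \eqn{g_c} scaled by the
#' soma-to-total area ratio \eqn{\rho}), a state layout naming the dynamic
#' states (one voltage per compartment, each dynamic gate, each calcium
#' pool), and a parameter registry holding every model parameter with its
#' unit, default value, prior bounds and free/fixed flag.  The registry is
#' the single source of truth during evaluation: \code{\link{drift}},
#' the simulator and the smoother all read parameter values from it (plus
#' any overrides), never from the structural objects.
#'
#' @slot name model identifier (\code{"hh1c"}, \code{"motoneuron2c"},
#'   \code{"b4"}, or a custom label).
#' @slot compartments ordered list of \code{CompartmentSpec}.
#' @slot couplingG coupling conductance default (0 for single compartment).
#' @slot somaAreaRatio ratio of soma area to total area, in (0, 1].
#' @slot stateLayout ordered character vector of state names.
#' @slot paramRegistry data.frame with columns \code{name}, \code{unit},
#'   \code{value}, \code{lower}, \code{upper}, \code{free}.
#'
#' @export
setClass("NeuronModel",
  representation(name = "character", compartments = "list",
                 couplingG = "numeric", somaAreaRatio = "numeric",
                 stateLayout = "character", paramRegistry = "data.frame"))

setValidity("NeuronModel", function(object) {
  msg <- character()
  if (anyDuplicated(object@stateLayout))
    msg <- c(msg, "state layout names must be unique")
  reg <- object@paramRegistry
  need <- c("name", "unit", "value", "lower", "upper", "free")
  if (!all(need %in% names(reg)))
    msg <- c(msg, "paramRegistry must have columns name/unit/value/lower/upper/free")
  else {
    if (anyDuplicated(reg$name)) msg <- c(msg, "registry names must be unique")
    bad <- reg$free & !(reg$lower < reg$upper)
    if (any(bad))
      msg <- c(msg, paste("free parameter without lower < upper:",
                          paste(reg$name[bad], collapse = ", ")))
    out <- reg$value < reg$lower | reg$value > reg$upper
    if (any(out))
      msg <- c(msg, paste("default outside bounds:",
                          paste(reg$name[out], collapse = ", ")))
  }
  if (object@somaAreaRatio <= 0 || object@somaAreaRatio > 1)
    msg <- c(msg, "somaAreaRatio must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Noise specification for stochastic simulation
#'
#' Intrinsic (system) noise enters the voltage equations as a diffusion term
#' with standard deviation \code{sigmaSys} per square-root millisecond;
#' observation noise is additive Gaussian on each recorded voltage sample.
#' Optional per-gate diffusion SDs default to zero, matching models in which
#' gate dynamics are treated as noiseless.
#'
#' @slot sigmaSys intrinsic-noise SD (voltage units per sqrt(ms)).
#' @slot sigmaObs observation-noise SD (mV).
#' @slot gateNoiseSd named numeric of per-gate SDs (default none).
#'
#' @export
setClass("NoiseSpec",
  representation(sigmaSys = "numeric", sigmaObs = "numeric",
                 gateNoiseSd = "numeric"),
  prototype(sigmaSys = 0, sigmaObs = 0, gateNoiseSd = numeric()))

setValidity("NoiseSpec", function(object) {
  if (object@sigmaSys < 0 || object@sigmaObs < 0 ||
      any(object@gateNoiseSd < 0))
    "noise standard deviations must be nonnegative"
  else TRUE
})

#' Random current-step protocol
#'
#' A piecewise-constant injected-current waveform: a sequence of steps with
#' i.i.d. uniform amplitudes and durations, the last step truncated so the
#' durations sum to the total duration.
#'
#' @slot steps data.frame with columns \code{amplitude} and \code{duration}
#'   (ms).
#' @slot totalDuration total duration (ms).
#'
#' @export
setClass("CurrentProtocol",
  representation(steps = "data.frame", totalDuration = "numeric"))

setValidity("CurrentProtocol", function(object) {
  msg <- character()
  if (any(object@steps$duration <= 0))
    msg <- c(msg, "step durations must be positive")
  if (abs(sum(object@steps$duration) - object@totalDuration) > 1e-8)
    msg <- c(msg, "durations must sum to totalDuration")
  if (length(msg)) msg else TRUE
})

#' Current-clamp recording
#'
#' Injected current and observed voltage channel(s) on a uniform sample grid.
#' Synthetic recordings also carry the true hidden-state trajectories and the
#' generating parameters in \code{meta}, for recovery scoring.
#'
#' @slot sampleInterval sampling interval (ms).
#' @slot iInj per-sample injected current, one column per compartment.
#' @slot y per-sample observed voltage, one column per observed channel.
#' @slot channelMap integer vector: the (1-based) compartment observed by
#'   each column of \code{y}.
#' @slot hidden matrix of true hidden states at sample times (synthetic
#'   recordings) or a 0-row matrix.
#' @slot meta list of provenance fields (model, seed, true parameters, noise
#'   levels, integration settings).
#'
#' @export
setClass("Recording",
  representation(sampleInterval = "numeric", iInj = "matrix", y = "matrix",
                 channelMap = "integer", hidden = "matrix", meta = "list"),
  prototype(hidden = matrix(numeric(), 0, 0), meta = list()))

setValidity("Recording", function(object) {
  msg <- character()
  if (nrow(object@iInj) != nrow(object@y))
    msg <- c(msg, "iInj and y must have the same number of rows")
  if (length(object@channelMap) != ncol(object@y))
    msg <- c(msg, "channelMap must have one entry per observed channel")
  if (object@sampleInterval <= 0)
    msg <- c(msg, "sampleInterval must be positive")
  if (length(msg)) msg else TRUE
})

#' Smoother configuration
#'
#' Settings for the fixed-lag self-organising smoother: ensemble size, lag,
#' integration step and substeps per observation, the ESS resampling
#' threshold (as a fraction of N), the three adaptation constants of the
#' evolution-strategy proposal, the prior interval of the per-particle scale
#' factor, covariance jitter, and the RNG seed.
#'
#' @slot nParticles number of particles N.
#' @slot lag fixed smoothing lag L in observation steps (0 = filtering).
#' @slot delta integration step (ms).
#' @slot k solver substeps per observation interval.
#' @slot resampleThreshold resample when ESS < threshold * N, in (0, 1].
#' @slot adaptA mean-adaptation constant a in [0, 1].
#' @slot adaptB covariance-adaptation constant b in [0, 1].
#' @slot adaptC log-normal scale adaptation constant c >= 0.
#' @slot tauInterval prior interval of the scale factor, c(lo, hi).
#' @slot jitter relative jitter added to the proposal covariance diagonal.
#' @slot C0 initial proposal covariance (matrix) or NULL for identity.
#' @slot seed RNG seed.
#' @slot maxDegenerate consecutive total-underflow steps tolerated before
#'   aborting.
#' @slot terminalFraction fraction of the run (from the end) averaged for the
#'   final parameter estimate.
#'
#' @export
setClass("SmootherConfig",
  representation(nParticles = "integer", lag = "integer", delta = "numeric",
                 k = "integer", resampleThreshold = "numeric",
                 adaptA = "numeric", adaptB = "numeric", adaptC = "numeric",
                 tauInterval = "numeric", jitter = "numeric", C0 = "ANY",
                 seed = "integer", maxDegenerate = "integer",
                 terminalFraction = "numeric"),
  prototype(nParticles = 1000L, lag = 100L, delta = 0.02, k = 5L,
            resampleThreshold = 0.5, adaptA = 0.1, adaptB = 0.1,
            adaptC = 0.1, tauInterval = c(0, 0.5), jitter = 1e-12,
            C0 = NULL, seed = 1L, maxDegenerate = 0L,
            terminalFraction = 0.2))

setValidity("SmootherConfig", function(object) {
  msg <- character()
  if (object@resampleThreshold <= 0 || object@resampleThreshold > 1)
    msg <- c(msg, "resampleThreshold must be in (0, 1]")
  if (length(object@tauInterval) != 2 || object@tauInterval[1] < 0 ||
      object@tauInterval[1] > object@tauInterval[2])
    msg <- c(msg, "tauInterval must be c(lo, hi) with 0 <= lo <= hi")
  if (object@adaptA < 0 || object@adaptA > 1 ||
      object@adaptB < 0 || object@adaptB > 1 || object@adaptC < 0)
    msg <- c(msg, "adaptation constants must satisfy a, b in [0,1], c >= 0")
  if (object@lag < 0) msg <- c(msg, "lag must be >= 0")
  if (object@delta <= 0 || object@k < 1)
    msg <- c(msg, "delta must be positive and k >= 1")
  if (object@terminalFraction <= 0 || object@terminalFraction > 1)
    msg <- c(msg, "terminalFraction must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Weighted particle ensemble with a fixed-lag trajectory buffer
#'
#' The in-R representation of the smoother's particle system, used by the
#' step-level operations (\code{\link{reweightEnsemble}},
#' \code{\link{resampleFixedLag}}, \code{\link{smoothedExpectation}},
#' \code{\link{selfOrganizingStep}}).  The production run loop lives in
#' compiled code; this class exposes the same mechanics at R level.
#'
#' @slot theta matrix (n x d) of free-parameter values per particle.
#' @slot tau numeric vector of per-particle scale factors.
#' @slot states matrix (n x S) of hidden states per particle (0 columns if
#'   unused).
#' @slot weights normalized importance weights (sum 1).
#' @slot buffer list of extended-state matrices, oldest first, at most
#'   lag + 1 entries; each is cbind(states, theta, tau).
#' @slot lag fixed lag L.
#'
#' @export
setClass("ParticleEnsemble",
  representation(theta = "matrix", tau = "numeric", states = "matrix",
                 weights = "numeric", buffer = "list", lag = "integer"),
  prototype(buffer = list(), lag = 0L))

setValidity("ParticleEnsemble", function(object) {
  msg <- character()
  n <- length(object@weights)
  if (abs(sum(object@weights) - 1) > 1e-12)
    msg <- c(msg, "weights must sum to 1")
  if (any(object@weights < 0)) msg <- c(msg, "weights must be nonnegative")
  if (nrow(object@theta) != n) msg <- c(msg, "theta must have n rows")
  if (length(object@tau) != n) msg <- c(msg, "tau must have length n")
  if (length(object@buffer) > object@lag + 1L)
    msg <- c(msg, "buffer cannot exceed lag + 1 entries")
  if (length(msg)) msg else TRUE
})

#' Result of a fixed-lag smoother run
#'
#' Time series of posterior expectations and SDs of the free parameters, the
#' fixed-lag smoothed expectations of the hidden states, the effective sample
#' size trace, adaptation diagnostics (mean scale factor, trace of the
#' proposal covariance, per-parameter bound-hit counts), the resampling event
#' log, and the terminal-window parameter estimate.
#'
#' @slot modelName name of the fitted model.
#' @slot freeParams names of the estimated parameters.
#' @slot times observation times (ms).
#' @slot thetaMean per-time posterior means of the free parameters.
#' @slot thetaSd per-time posterior SDs.
#' @slot smoothedStates fixed-lag smoothed state expectations; for
#'   multi-trace fits, columns are grouped per trace.
#' @slot ess effective-sample-size trace.
#' @slot tauMean per-time ensemble mean of the scale factor.
#' @slot traceC per-time trace of the shared proposal covariance.
#' @slot resampled logical: resampling event at each observation time.
#' @slot boundHits per-parameter count of proposal samples clamped at a
#'   prior bound.
#' @slot finalEstimate terminal-window mean of the parameter chains.
#' @slot finalSd terminal-window SD of the parameter chains.
#' @slot nTraces number of traces fitted jointly.
#' @slot config the \code{SmootherConfig} used.
#' @slot priorBox the prior bounds actually used (matrix with rows lower,
#'   upper).
#'
#' @export
setClass("FitResult",
  representation(modelName = "character", freeParams = "character",
                 times = "numeric", thetaMean = "matrix", thetaSd = "matrix",
                 smoothedStates = "matrix", ess = "numeric",
                 tauMean = "numeric", traceC = "numeric",
                 resampled = "logical", boundHits = "integer",
                 finalEstimate = "numeric", finalSd = "numeric",
                 nTraces = "integer", config = "SmootherConfig",
                 priorBox = "matrix"))

setValidity("FitResult", function(object) {
  n <- length(object@times)
  if (nrow(object@thetaMean) != n || length(object@ess) != n)
    "per-time slots must match the number of observation times"
  else TRUE
})

#' Recovery-experiment scenario
#'
#' A complete description of one simulation study: the model and true
#' parameters used to generate synthetic recordings, the free-parameter set
#' and prior box used during inference, the stimulation protocol and noise
#' levels, the smoother configuration, and the replicate plan.
#'
#' @slot name scenario label.
#' @slot modelName registered model name.
#' @slot thetaTrue named numeric of parameter overrides used for generation.
#' @slot freeParams character vector of estimated parameters.
#' @slot priorBox matrix with rows \code{lower} and \code{upper} (columns =
#'   free parameters) or 0-row matrix to use the registry bounds.
#' @slot protocol list: \code{ampMin}, \code{ampMax}, \code{durMin},
#'   \code{durMax}, \code{totalT} (ms); used per stimulated compartment.
#' @slot noise \code{NoiseSpec} used for generation.
#' @slot config \code{SmootherConfig}.
#' @slot nReplicates number of replicate fits.
#' @slot seedBase base seed; replicate r uses seedBase + r.
#'
#' @export
setClass("Scenario",
  representation(name = "character", modelName = "character",
                 thetaTrue = "numeric", freeParams = "character",
                 priorBox = "matrix", protocol = "list", noise = "NoiseSpec",
                 config = "SmootherConfig", nReplicates = "integer",
                 seedBase = "integer"),
  prototype(thetaTrue = numeric(), priorBox = matrix(numeric(), 0, 0),
            nReplicates = 1L, seedBase = 1L))

#' Aggregated report of a recovery experiment
#'
#' @slot scenarioName scenario label.
#' @slot parameters data.frame with one row per (replicate, parameter):
#'   true value, terminal estimate, normalized discrepancy, terminal SD,
#'   bound-hit fraction.
#' @slot runs data.frame with one row per replicate: smoothed-voltage RMSE,
#'   ESS summary, resample count, success flag.
#'
#' @export
setClass("RecoveryReport",
  representation(scenarioName = "character", parameters = "data.frame",
                 runs = "data.frame"))
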