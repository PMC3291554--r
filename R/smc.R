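#' @include AllClasses.R
NULL

#' Gaussian log observation density
#'
#' Sum over channels of Gaussian log densities of the observed voltages,
#' centred at the corresponding compartment voltages of a state vector.
#'
#' @param y observed vector (one value per channel).
#' @param vComp voltage(s) of the observed compartment(s), matched to
#'   \code{y}.
#' @param sigmaObs observation-noise SD, positive.
#' @return log probability density.
#' @examples
#' logObservationDensity(-60, -60, 1)  # -0.5 * log(2 * pi)
#' @export
logObservationDensity <- function(y, vComp, sigmaObs) {
  if (sigmaObs <= 0) stop("sigmaObs must be positive")
  sum(stats::dnorm(y, mean = vComp, sd = sigmaObs, log = TRUE))
}

#' Normalize log importance weights
#'
#' Log-sum-exp normalization with max subtraction.  All-underflowed input is
#' an error (a degenerate ensemble is reported, never silently reset).
#'
#' @param logw log weights.
#' @return normalized weights summing to one.
#' @export
normalizeLogWeights <- function(logw) {
  m <- max(logw)
  if (!is.finite(m))
    stop("degenerate ensemble: all importance weights underflowed to zero")
  w <- exp(logw - m)
  w / sum(w)
}

#' Multiply weights by likelihoods and renormalize
#'
#' @param weights current normalized weights.
#' @param loglik per-particle log likelihood of the new observation.
#' @return updated normalized weights.
#' @export
reweight <- function(weights, loglik) {
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must be normalized")
  normalizeLogWeights(log(weights) + loglik)
}

#' Effective sample size
#'
#' \eqn{1/\sum_i w_i^2} for normalized weights; lies in [1, N].
#'
#' @param weights normalized importance weights.
#' @return the effective number of particles.
#' @export
effectiveSampleSize <- function(weights) {
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must be normalized to sum 1")
  1 / sum(weights^2)
}

#' Systematic resampling
#'
#' Draws N ancestor indices with a single uniform offset; expected copy
#' counts equal N times the weights, and with uniform weights every particle
#' is copied exactly once.
#'
#' @param weights normalized weights.
#' @param u optional uniform offset in [0, 1) (drawn from the RNG when
#'   missing); exposed for testing.
#' @return integer vector of ancestor indices.
#' @export
systematicResample <- function(weights, u = stats::runif(1)) {
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must be normalized to sum 1")
  .cppSystematicResample(weights, u)
}

#' Construct a particle ensemble
#'
#' @param theta matrix (n x d) of free-parameter values (or a numeric
#'   vector for d = 1).
#' @param tau per-particle scale factors.
#' @param weights normalized weights (default uniform).
#' @param states optional matrix (n x S) of hidden states.
#' @param lag fixed lag L.
#' @return a \code{\link{ParticleEnsemble}} with an empty trajectory buffer.
#' @export
particleEnsemble <- function(theta, tau = rep(0.1, nrow(theta)),
                             weights = NULL, states = NULL, lag = 0L) {
  if (is.null(dim(theta))) theta <- matrix(theta, ncol = 1)
  n <- nrow(theta)
  if (is.null(weights)) weights <- rep(1 / n, n)
  if (is.null(states)) states <- matrix(numeric(), n, 0)
  new("ParticleEnsemble", theta = theta, tau = tau, states = states,
      weights = weights, buffer = list(), lag = as.integer(lag))
}

# extended state snapshot of the current particles
.extState <- function(ens) cbind(ens@states, ens@theta, ens@tau)

#' Push the current extended states onto the lag buffer
#'
#' The buffer keeps at most lag + 1 snapshots (oldest dropped).
#'
#' @param ens a \code{\link{ParticleEnsemble}}.
#' @return the updated ensemble.
#' @export
pushBuffer <- function(ens) {
  buf <- c(ens@buffer, list(.extState(ens)))
  if (length(buf) > ens@lag + 1L) buf <- buf[-1L]
  ens@buffer <- buf
  ens
}

#' Propagate an ensemble through the stochastic model dynamics
#'
#' Advances each particle's hidden state through \code{k} Euler-Maruyama
#' substeps using that particle's own parameter values.  The proposal is
#' the transition density, so the importance weights are left untouched.
#'
#' @param ens a \code{\link{ParticleEnsemble}} whose \code{states} columns
#'   follow the model's \code{\link{stateLayout}} and whose \code{theta}
#'   columns are named with registry parameter names.
#' @param model a \code{\link{NeuronModel}}.
#' @param iInj injected current per compartment, held constant over the
#'   observation interval.
#' @param noise a \code{\link{NoiseSpec}}; when \code{sigma_sys} is one of
#'   the \code{theta} columns each particle uses its own value instead.
#' @param delta integration step (ms).
#' @param k substeps per observation interval.
#' @return the ensemble with advanced states and unchanged weights.
#' @export
propagateEnsemble <- function(ens, model, iInj, noise = noiseSpec(),
                              delta = 0.02, k = 5L) {
  n <- length(ens@weights)
  if (!n || !ncol(ens@states)) stop("cannot propagate an empty ensemble")
  thNames <- colnames(ens@theta)
  for (i in seq_len(n)) {
    ov <- if (length(thNames)) stats::setNames(ens@theta[i, ], thNames)
          else NULL
    nz <- if ("sigma_sys" %in% thNames)
      noiseSpec(ov[["sigma_sys"]], noise@sigmaObs, noise@gateNoiseSd)
    else noise
    x <- ens@states[i, ]
    for (q in seq_len(k))
      x <- emStep(model, x, iInj, nz, delta, overrides = ov)
    ens@states[i, ] <- x
  }
  ens
}

#' Reweight an ensemble with new log likelihoods
#'
#' @param ens a \code{\link{ParticleEnsemble}}.
#' @param loglik per-particle log likelihood.
#' @return the ensemble with updated weights.
#' @export
reweightEnsemble <- function(ens, loglik) {
  ens@weights <- reweight(ens@weights, loglik)
  ens
}

#' Fixed-lag resampling of whole trajectories
#'
#' Systematic resampling of particle indices; the entire lag-window
#' trajectory (states, parameters, scale factors) of each selected particle
#' is copied, and weights are reset to 1/N.
#'
#' @param ens a \code{\link{ParticleEnsemble}}.
#' @param u optional uniform offset (see \code{\link{systematicResample}}).
#' @return the resampled ensemble.
#' @export
resampleFixedLag <- function(ens, u = stats::runif(1)) {
  idx <- systematicResample(ens@weights, u)
  ens@theta <- ens@theta[idx, , drop = FALSE]
  ens@tau <- ens@tau[idx]
  if (ncol(ens@states)) ens@states <- ens@states[idx, , drop = FALSE]
  ens@buffer <- lapply(ens@buffer, function(b) b[idx, , drop = FALSE])
  ens@weights <- rep(1 / length(idx), length(idx))
  ens
}

#' Smoothed expectation from the lag buffer
#'
#' Weighted mean of a function of the extended state stored
#' \code{lagOffset} observation steps back.
#'
#' @param ens a \code{\link{ParticleEnsemble}} whose buffer has been filled
#'   via \code{\link{pushBuffer}}.
#' @param fn function applied to each particle's extended-state row
#'   (states, theta, tau); must return a scalar.
#' @param lagOffset how many steps back (0 = current filter estimate).
#' @return the weighted mean.
#' @export
smoothedExpectation <- function(ens, fn, lagOffset = 0L) {
  depth <- length(ens@buffer)
  if (lagOffset >= depth)
    stop(sprintf("buffer not ready: depth %d cannot serve lag offset %d",
                 depth, lagOffset), call. = FALSE)
  snap <- ens@buffer[[depth - lagOffset]]
  vals <- apply(snap, 1, fn)
  sum(ens@weights * vals)
}

setMethod("show", "ParticleEnsemble", function(object) {
  cat(sprintf("ParticleEnsemble: %d particles, %d parameter(s), lag %d, ESS %.1f\n",
              length(object@weights), ncol(object@theta), object@lag,
              effectiveSampleSize(object@weights)))
})

#' Generic bootstrap particle filter
#'
#' A minimal bootstrap filter for arbitrary state-space models expressed as
#' two functions, using the package's weighting and systematic-resampling
#' machinery.  Used for validating the particle machinery against
#' closed-form filters on linear-Gaussian models.
#'
#' @param y vector of observations.
#' @param init function(n) returning n initial state samples.
#' @param propagate function(x) advancing a vector of particle states one
#'   step (stochastically).
#' @param loglik function(x, y) per-particle log observation density.
#' @param n number of particles.
#' @param resampleThreshold resample when ESS < threshold * n.
#' @return list with \code{mean} and \code{sd} (filter mean/SD per time) and
#'   \code{ess}.
#' @export
bootstrapFilter <- function(y, init, propagate, loglik, n = 1000,
                            resampleThreshold = 0.5) {
  x <- init(n)
  w <- rep(1 / n, n)
  T <- length(y)
  m <- s <- ess <- numeric(T)
  for (t in seq_len(T)) {
    x <- propagate(x)
    w <- reweight(w, loglik(x, y[t]))
    m[t] <- sum(w * x)
    s[t] <- sqrt(sum(w * (x - m[t])^2))
    ess[t] <- effectiveSampleSize(w)
    if (ess[t] < resampleThreshold * n) {
      x <- x[systematicResample(w)]
      w <- rep(1 / n, n)
    }
  }
  list(mean = m, sd = s, ess = ess)
}
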