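#' @include smc.R
NULL

#' Weighted mean and covariance of the parameter sample
#'
#' Population-convention weighted moments of the per-particle parameter
#' vectors: \eqn{E = \sum_i w_i \theta_i}, \eqn{C = \sum_i w_i (\theta_i -
#' E)(\theta_i - E)^T}.
#'
#' @param theta matrix (n x d) of parameter values (vector accepted for
#'   d = 1).
#' @param weights normalized weights.
#' @return list with \code{mean} (length d) and \code{cov} (d x d).
#' @export
weightedMoments <- function(theta, weights) {
  if (is.null(dim(theta))) theta <- matrix(theta, ncol = 1)
  if (abs(sum(weights) - 1) > 1e-8)
    stop("weights must be normalized to sum 1")
  m <- colSums(theta * weights)
  cent <- sweep(theta, 2, m)
  list(mean = m, cov = crossprod(cent * weights, cent) / 1)
}

#' Log-normal update of the per-particle scale factor
#'
#' \eqn{\tau' = \tau e^{c\xi}} with standard-normal \eqn{\xi}, clamped to
#' the prior interval.
#'
#' @param tau current scale factor(s), positive.
#' @param c adaptation constant (0 leaves tau unchanged).
#' @param tauInterval \code{c(lo, hi)} prior interval.
#' @return updated scale factor(s).
#' @export
updateScale <- function(tau, c, tauInterval) {
  if (tauInterval[1] > tauInterval[2])
    stop("tau interval must satisfy lo <= hi")
  tnew <- tau * exp(c * stats::rnorm(length(tau)))
  pmin(pmax(tnew, tauInterval[1]), tauInterval[2])
}

#' Per-particle proposal mean update
#'
#' Convex combination drifting each particle's parameter vector towards the
#' weighted ensemble mean with rate \code{a}: \eqn{m_i = \theta_i + a(E -
#' \theta_i)}.
#'
#' @param thetaPrev matrix (n x d) or vector of previous parameter values.
#' @param ensembleMean weighted ensemble mean (length d).
#' @param a adaptation constant in [0, 1].
#' @return proposal mean(s), same shape as \code{thetaPrev}.
#' @export
updateMean <- function(thetaPrev, ensembleMean, a) {
  if (a < 0 || a > 1) stop("adaptation constant a must be in [0, 1]")
  if (is.null(dim(thetaPrev)))
    return(thetaPrev + a * (ensembleMean - thetaPrev))
  thetaPrev + a * sweep(-thetaPrev, 2, ensembleMean, `+`)
}

#' Shared proposal covariance update
#'
#' \eqn{C = (1-b) C_{prev} + b\, \mathrm{Cov}}, then a small multiple of the
#' identity is added before factorization so the result stays positive
#' definite even when the ensemble covariance collapses.
#'
#' @param cPrev previous proposal covariance (symmetric).
#' @param ensembleCov weighted ensemble covariance (symmetric).
#' @param b adaptation constant in [0, 1].
#' @param jitter relative jitter (times mean diagonal, floored at 1e-300).
#' @return updated covariance, symmetric positive definite.
#' @export
updateCovariance <- function(cPrev, ensembleCov, b, jitter = 1e-12) {
  if (b < 0 || b > 1) stop("adaptation constant b must be in [0, 1]")
  C <- (1 - b) * cPrev + b * ensembleCov
  d <- nrow(C)
  jit <- max(jitter * mean(diag(C)), 1e-300)
  C <- C + jit * diag(d)
  ok <- tryCatch({ chol(C); TRUE }, error = function(e) FALSE)
  tries <- 0
  while (!ok && tries < 8) {
    jit <- jit * 100
    C <- C + jit * diag(d)
    ok <- tryCatch({ chol(C); TRUE }, error = function(e) FALSE)
    tries <- tries + 1
  }
  if (!ok)
    stop(sprintf("covariance factorization failed (condition number %.3g)",
                 kappa(C)))
  (C + t(C)) / 2
}

#' Sample new parameter vectors from the adaptive proposal
#'
#' \eqn{\theta = \mathrm{clamp}(m + \tau L^T \xi)} with \eqn{LL^T = C} and
#' standard-normal \eqn{\xi}; the proposal covariance is \eqn{\tau^2 C}.
#' With the adaptation switched off (a = 0, fixed tau) this is a plain
#' multivariate Gaussian random walk centred at the previous value.
#'
#' @param m proposal mean(s): vector (d) or matrix (n x d).
#' @param C shared covariance (d x d), factorizable.
#' @param tau scale factor (scalar or length n).
#' @param bounds matrix with rows \code{lower} and \code{upper} (d columns).
#' @return sampled parameters, clamped componentwise into the bounds; same
#'   shape as \code{m}.
#' @export
sampleParameters <- function(m, C, tau, bounds) {
  vec <- is.null(dim(m))
  if (vec) m <- matrix(m, ncol = length(m))
  n <- nrow(m); d <- ncol(m)
  R <- chol(C)
  xi <- matrix(stats::rnorm(n * d), n, d)
  draws <- m + (xi %*% R) * tau
  loM <- matrix(bounds["lower", ], n, d, byrow = TRUE)
  hiM <- matrix(bounds["upper", ], n, d, byrow = TRUE)
  draws <- pmin(pmax(draws, loM), hiM)
  if (vec) draws[1, ] else draws
}

#' One self-organising adaptation step
#'
#' Executes the per-iteration parameter-evolution stage in its prescribed
#' order: ensemble moments, per-particle scale update, per-particle mean,
#' shared covariance, parameter sampling, and finally (optionally) hidden
#' state propagation conditioned on the new parameters.  Selection pressure
#' arises only through the subsequent reweighting and resampling.
#'
#' @param ens a \code{\link{ParticleEnsemble}}.
#' @param adaptation list with element \code{C} (shared covariance).
#' @param config a \code{\link{SmootherConfig}} (adaptation constants, tau
#'   interval, jitter, bounds are read from \code{bounds}).
#' @param bounds matrix with rows \code{lower}/\code{upper} for the free
#'   parameters.
#' @param propagate optional function(states, theta) returning new states.
#' @return list with the updated \code{ensemble} and \code{adaptation}.
#' @export
selfOrganizingStep <- function(ens, adaptation, config, bounds,
                               propagate = NULL) {
  d <- ncol(ens@theta)
  if (d > 0) {
    mom <- weightedMoments(ens@theta, ens@weights)              # 1a
    ens@tau <- updateScale(ens@tau, config@adaptC, config@tauInterval) # 1b
    m <- updateMean(ens@theta, mom$mean, config@adaptA)         # 1c
    adaptation$C <- updateCovariance(adaptation$C, mom$cov,
                                     config@adaptB, config@jitter) # 1d
    ens@theta <- sampleParameters(m, adaptation$C, ens@tau, bounds) # 1e
  }
  if (!is.null(propagate))
    ens@states <- propagate(ens@states, ens@theta)              # 1f
  list(ensemble = ens, adaptation = adaptation)
}
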