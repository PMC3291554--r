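#' @include models.R
NULL

#' Construct a noise specification
#'
#' @param sigmaSys intrinsic-noise SD applied to each voltage equation
#'   (voltage units per sqrt(ms)).
#' @param sigmaObs observation-noise SD (mV).
#' @param gateNoiseSd optional named numeric of per-gate diffusion SDs
#'   (defaults to none: gate dynamics noiseless).
#' @return a \code{\link{NoiseSpec}}.
#' @export
noiseSpec <- function(sigmaSys = 0, sigmaObs = 0, gateNoiseSd = numeric()) {
  new("NoiseSpec", sigmaSys = sigmaSys, sigmaObs = sigmaObs,
      gateNoiseSd = gateNoiseSd)
}

# per-state diffusion SD vector in layout order (voltages get sigmaSys)
.gateSdVector <- function(model, noise) {
  lay <- stateLayout(model)
  sd <- stats::setNames(numeric(length(lay)), lay)
  if (length(noise@gateNoiseSd)) {
    bad <- setdiff(names(noise@gateNoiseSd), lay)
    if (length(bad)) stop("unknown gate in gateNoiseSd: ",
                          paste(bad, collapse = ", "))
    sd[names(noise@gateNoiseSd)] <- noise@gateNoiseSd
  }
  sd
}

#' One Euler-Maruyama step
#'
#' \eqn{x' = x + f(x)\,\delta + \sqrt{\delta}\,\Sigma\,\xi} with standard
#' normal \eqn{\xi}; intrinsic noise enters the voltage equations, optional
#' per-gate noise the gate equations.  Gates are clipped to [0, 1] and
#' calcium to be nonnegative after the update.
#'
#' @param model a \code{\link{NeuronModel}}.
#' @param x current state (layout order).
#' @param iInj injected current per compartment.
#' @param noise a \code{\link{NoiseSpec}}.
#' @param delta time step (ms), positive.
#' @param overrides named parameter overrides.
#' @return the updated state vector.
#' @export
emStep <- function(model, x, iInj, noise = noiseSpec(), delta = 0.02,
                   overrides = NULL) {
  if (delta <= 0) stop("delta must be positive")
  d <- drift(model, x, iInj, overrides)
  if (any(!is.finite(d))) {
    bad <- model@stateLayout[!is.finite(d)][1]
    stop(sprintf("numerical instability: non-finite drift for state '%s'", bad))
  }
  lay <- stateLayout(model)
  nc <- length(model@compartments)
  xn <- as.numeric(x) + d * delta
  xn[seq_len(nc)] <- xn[seq_len(nc)] +
    sqrt(delta) * noise@sigmaSys * stats::rnorm(nc)
  gsd <- .gateSdVector(model, noise)
  noisy <- which(gsd > 0)
  if (length(noisy))
    xn[noisy] <- xn[noisy] + sqrt(delta) * gsd[noisy] * stats::rnorm(length(noisy))
  isGate <- .stateKinds(model) == "gate"
  xn[isGate] <- pmin(pmax(xn[isGate], 0), 1)
  isCa <- .stateKinds(model) == "ca"
  xn[isCa] <- pmax(xn[isCa], 0)
  stats::setNames(xn, lay)
}

.stateKinds <- function(model) {
  lay <- stateLayout(model)
  kinds <- rep("gate", length(lay))
  kinds[seq_len(length(model@compartments))] <- "v"
  kinds[grepl("^ca", lay)] <- "ca"
  kinds
}

#' Generate a random current-step protocol
#'
#' Step amplitudes and durations are i.i.d. uniform on the given ranges;
#' the final step is truncated so the durations sum to \code{totalT}.
#'
#' @param ampMin,ampMax amplitude range (current units).
#' @param durMin,durMax duration range (ms), \code{0 < durMin <= durMax}.
#' @param totalT total protocol duration (ms).
#' @param seed optional RNG seed for a reproducible protocol.
#' @return a \code{\link{CurrentProtocol}}.
#' @examples
#' p <- generateProtocol(-5, 20, 10, 100, totalT = 1000, seed = 1)
#' @export
generateProtocol <- function(ampMin, ampMax, durMin, durMax, totalT,
                             seed = NULL) {
  if (!(ampMin < ampMax)) stop("need ampMin < ampMax")
  if (!(durMin > 0 && durMin <= durMax)) stop("need 0 < durMin <= durMax")
  if (totalT <= 0) stop("totalT must be positive")
  if (!is.null(seed)) set.seed(seed)
  amps <- numeric(); durs <- numeric(); tot <- 0
  while (tot < totalT) {
    amps <- c(amps, stats::runif(1, ampMin, ampMax))
    d <- stats::runif(1, durMin, durMax)
    durs <- c(durs, d)
    tot <- tot + d
  }
  durs[length(durs)] <- durs[length(durs)] - (tot - totalT)
  if (durs[length(durs)] <= 0) { # truncation consumed the final step
    amps <- amps[-length(amps)]; durs <- durs[-length(durs)]
  }
  new("CurrentProtocol",
      steps = data.frame(amplitude = amps, duration = durs),
      totalDuration = sum(durs))
}

#' Evaluate a protocol at given times
#'
#' @param protocol a \code{\link{CurrentProtocol}}.
#' @param times times (ms) at which to evaluate the injected current.
#' @return numeric vector of amplitudes.
#' @export
protocolCurrent <- function(protocol, times) {
  ends <- cumsum(protocol@steps$duration)
  # step s is active on [start_s, end_s)
  i <- findInterval(times, c(0, ends))
  i <- pmin(pmax(i, 1L), nrow(protocol@steps))
  protocol@steps$amplitude[i]
}

#' Simulate a synthetic current-clamp recording
#'
#' Integrates the stochastic model with the Euler-Maruyama scheme at step
#' \code{delta}, taking \code{k} substeps per output sample (sampling
#' interval \code{k * delta}), then adds Gaussian observation noise to the
#' observed compartment voltage(s).  The true hidden trajectories are stored
#' alongside for recovery scoring.
#'
#' @param model a \code{\link{NeuronModel}}.
#' @param protocol a \code{\link{CurrentProtocol}}, or a list with one
#'   protocol per compartment (unsupplied compartments receive zero
#'   current).
#' @param noise a \code{\link{NoiseSpec}}.
#' @param thetaTrue named parameter overrides used for generation.
#' @param delta integration step (ms); default 0.02.
#' @param k integer substeps per sample; default 5 (0.1 ms sampling).
#' @param observedCompartments integer vector of observed compartments.
#' @param v0 initial holding potential; defaults to the leak reversal.
#' @param seed RNG seed.
#' @return a \code{\link{Recording}}.
#' @examples
#' m <- buildModel("hh1c")
#' p <- generateProtocol(-5, 20, 10, 100, totalT = 200, seed = 1)
#' rec <- simulateRecording(m, p, noiseSpec(0.5, 1), seed = 1)
#' @export
simulateRecording <- function(model, protocol, noise = noiseSpec(),
                              thetaTrue = NULL, delta = 0.02, k = 5L,
                              observedCompartments = 1L, v0 = NULL,
                              seed = NULL) {
  k <- as.integer(k)
  if (k < 1L) stop("k must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  nc <- length(model@compartments)
  protos <- if (is(protocol, "CurrentProtocol")) c(list(protocol),
              rep(list(NULL), nc - 1L)) else protocol
  if (length(protos) != nc)
    stop("supply one protocol per compartment (or a single one for compartment 1)")
  totalT <- max(vapply(Filter(Negate(is.null), protos), slot, 0,
                       "totalDuration"))
  dt <- k * delta
  nsamp <- floor(totalT / dt)
  times <- (seq_len(nsamp) - 1L) * dt
  iinj <- matrix(0, nsamp, nc)
  for (ci in seq_len(nc))
    if (!is.null(protos[[ci]])) iinj[, ci] <- protocolCurrent(protos[[ci]], times)

  p <- .resolveParams(model, thetaTrue)
  if (is.null(v0)) v0 <- p[["e_leak"]]
  desc <- compileModel(model)
  x0 <- .cppSteadyInit(desc, rep_len(as.numeric(v0), nc), as.numeric(p))
  # zero-order hold of the per-sample current over the k substeps
  iinjSub <- iinj[rep(seq_len(nsamp - 1L), each = k), , drop = FALSE]
  states <- .cppSimulate(desc, as.numeric(p), x0, iinjSub, delta, k,
                         noise@sigmaSys, .gateSdVector(model, noise))
  colnames(states) <- stateLayout(model)
  obs <- as.integer(observedCompartments)
  y <- states[, obs, drop = FALSE] +
    noise@sigmaObs * matrix(stats::rnorm(nsamp * length(obs)), nsamp)
  colnames(y) <- paste0("v_obs_", vapply(model@compartments[obs], slot, "",
                                         "name"))
  colnames(iinj) <- paste0("i_inj_", vapply(model@compartments, slot, "",
                                            "name"))
  new("Recording", sampleInterval = dt, iInj = iinj, y = y,
      channelMap = obs, hidden = states,
      meta = list(model = model@name, seed = seed,
                  theta_true = as.list(thetaTrue),
                  sigma_sys = noise@sigmaSys, sigma_obs = noise@sigmaObs,
                  delta = delta, k = k))
}

#' @rdname sampleTimes
setMethod("sampleTimes", "Recording", function(object)
  (seq_len(nrow(object@y)) - 1L) * object@sampleInterval)

#' @rdname observedVoltage
setMethod("observedVoltage", "Recording", function(object) object@y)

#' @rdname injectedCurrent
setMethod("injectedCurrent", "Recording", function(object) object@iInj)

#' @rdname hiddenStates
setMethod("hiddenStates", "Recording", function(object) object@hidden)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d samples at %g ms (%g ms total), %d channel(s)%s\n",
              nrow(object@y), object@sampleInterval,
              nrow(object@y) * object@sampleInterval, ncol(object@y),
              if (nrow(object@hidden)) ", with true hidden states" else ""))
  if (!is.null(object@meta$model))
    cat("  model:", object@meta$model, "\n")
})
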