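#' @include multitrace.R
NULL

#' Normalize terminal parameter estimates
#'
#' Centres a chain of estimates at the true value (zero means perfect
#' recovery) and scales by the absolute window-average estimate, making
#' discrepancies comparable across parameters with different units and
#' magnitudes: \eqn{z_t = (\theta_t - \theta^*)/|\bar\theta|}.  When the
#' truth is unknown (real-data mode) centring uses the window mean, so a
#' constant chain maps to zero.
#'
#' @param estimates numeric vector: the estimate chain over the terminal
#'   window.
#' @param thetaTrue true value, or \code{NULL} in unknown-truth mode.
#' @param priorWidth fallback scale used (with a warning) when the window
#'   average is zero.
#' @return normalized values, same length as \code{estimates}.
#' @examples
#' normalizeEstimates(rep(120, 5), thetaTrue = 120)  # all zero
#' @export
normalizeEstimates <- function(estimates, thetaTrue = NULL,
                               priorWidth = NULL) {
  if (!length(estimates)) stop("empty estimate window")
  m <- mean(estimates)
  scale <- abs(m)
  if (scale == 0) {
    if (is.null(priorWidth))
      stop("window average is zero; supply priorWidth as a fallback scale")
    warning("window average is zero; scaling by the prior-interval width")
    scale <- priorWidth
  }
  center <- if (is.null(thetaTrue)) m else thetaTrue
  (estimates - center) / scale
}

#' Detect spike times
#'
#' Upward crossings of a threshold with a refractory lockout.
#'
#' @param v voltage trace (mV).
#' @param times sample times (ms).
#' @param threshold crossing threshold (mV); default 0.
#' @param refractory lockout after each detected spike (ms); default 2.
#' @return numeric vector of spike times.
#' @export
spikeTimes <- function(v, times, threshold = 0, refractory = 2) {
  up <- which(v[-1] > threshold & v[-length(v)] <= threshold) + 1L
  if (!length(up)) return(numeric())
  keep <- times[up[1]]
  for (t in times[up[-1]])
    if (t - keep[length(keep)] >= refractory) keep <- c(keep, t)
  keep
}

#' Construct a recovery scenario
#'
#' @param name scenario label.
#' @param modelName registered model name (see \code{\link{buildModel}}).
#' @param freeParams parameters estimated during the fit.
#' @param protocol list with \code{ampMin}, \code{ampMax}, \code{durMin},
#'   \code{durMax}, \code{totalT} (ms).
#' @param noise \code{\link{NoiseSpec}} used for generation.
#' @param config \code{\link{SmootherConfig}}.
#' @param thetaTrue named generation overrides (empty = registry defaults).
#' @param priorBox optional bounds override for the free parameters.
#' @param nReplicates replicate count.
#' @param seedBase base seed; replicate r uses seeds derived from
#'   \code{seedBase + r}.
#' @return a \code{\link{Scenario}}.
#' @export
scenario <- function(name, modelName, freeParams, protocol, noise, config,
                     thetaTrue = numeric(), priorBox = NULL,
                     nReplicates = 1, seedBase = 1) {
  if (is.null(priorBox)) priorBox <- matrix(numeric(), 0, 0)
  new("Scenario", name = name, modelName = modelName,
      thetaTrue = thetaTrue, freeParams = freeParams, priorBox = priorBox,
      protocol = protocol, noise = noise, config = config,
      nReplicates = as.integer(nReplicates), seedBase = as.integer(seedBase))
}

# Generate the recording(s) for one scenario replicate; current is injected
# into every compartment (independent protocols), and every compartment is
# observed, mirroring the two-compartment experimental design.
.scenarioRecording <- function(model, sc, repSeed) {
  nc <- length(model@compartments)
  pr <- sc@protocol
  protos <- lapply(seq_len(nc), function(ci)
    generateProtocol(pr$ampMin, pr$ampMax, pr$durMin, pr$durMax, pr$totalT,
                     seed = deriveSeed(repSeed, paste0("protocol", ci))))
  simulateRecording(model, protos, sc@noise, thetaTrue =
                      if (length(sc@thetaTrue)) sc@thetaTrue else NULL,
                    delta = sc@config@delta, k = sc@config@k,
                    observedCompartments = seq_len(nc),
                    seed = deriveSeed(repSeed, "recording"))
}

# Root-mean-square error of the smoothed voltage(s) against the true hidden
# voltages of a synthetic recording.
.smoothedVoltageRmse <- function(fit, rec, model) {
  nc <- length(model@compartments)
  vcols <- seq_len(nc)
  est <- fit@smoothedStates[, vcols, drop = FALSE]
  truth <- rec@hidden[, vcols, drop = FALSE]
  sqrt(mean((est - truth)^2))
}

#' Run a recovery scenario
#'
#' Generates synthetic recordings, fits each replicate with the fixed-lag
#' self-organising smoother, and aggregates per-parameter recovery
#' statistics.  Replicates that abort (degenerate ensembles, instability)
#' are recorded as failures without stopping the scenario.  Fully seeded:
#' the same scenario and seed give identical reports.
#'
#' @param sc a \code{\link{Scenario}}.
#' @return a \code{\link{RecoveryReport}}.
#' @export
runScenario <- function(sc) {
  model <- buildModel(sc@modelName)
  truth <- .resolveParams(model,
                          if (length(sc@thetaTrue)) sc@thetaTrue else NULL)
  priorBox <- if (nrow(sc@priorBox)) sc@priorBox else NULL
  params <- NULL; runs <- NULL
  for (r in seq_len(sc@nReplicates)) {
    repSeed <- sc@seedBase + r
    rec <- .scenarioRecording(model, sc, repSeed)
    cfg <- sc@config
    cfg@seed <- deriveSeed(repSeed, "smoother")
    fit <- tryCatch(
      runFixedLagSmoother(model, rec, sc@freeParams, cfg,
                          priorBox = priorBox),
      error = function(e) e)
    if (inherits(fit, "error")) {
      runs <- rbind(runs, data.frame(replicate = r, ok = FALSE,
                                     message = conditionMessage(fit),
                                     v_rmse = NA_real_, ess_min = NA_real_,
                                     ess_mean = NA_real_, n_resample = NA))
      next
    }
    nobs <- length(fit@times)
    win <- seq.int(max(1L, ceiling(nobs * (1 - cfg@terminalFraction))), nobs)
    for (pn in sc@freeParams) {
      chain <- fit@thetaMean[win, pn]
      tv <- truth[[pn]]
      nd <- normalizeEstimates(chain, thetaTrue = tv,
                               priorWidth = diff(paramBounds(model, pn)))
      params <- rbind(params, data.frame(
        replicate = r, parameter = pn, true = tv,
        estimate = fit@finalEstimate[[pn]],
        norm_discrepancy = mean(nd),
        rel_error = if (tv != 0) abs(fit@finalEstimate[[pn]] - tv) / abs(tv)
                    else NA_real_,
        terminal_sd = fit@finalSd[[pn]],
        bound_hit_frac = fit@boundHits[match(pn, sc@freeParams)] /
          (cfg@nParticles * max(nobs - 1, 1))))
    }
    runs <- rbind(runs, data.frame(replicate = r, ok = TRUE, message = "",
                                   v_rmse = .smoothedVoltageRmse(fit, rec, model),
                                   ess_min = min(fit@ess),
                                   ess_mean = mean(fit@ess),
                                   n_resample = sum(fit@resampled)))
  }
  new("RecoveryReport", scenarioName = sc@name,
      parameters = if (is.null(params)) data.frame() else params,
      runs = if (is.null(runs)) data.frame() else runs)
}

setMethod("show", "RecoveryReport", function(object) {
  cat(sprintf("RecoveryReport '%s': %d replicate(s), %d ok\n",
              object@scenarioName, nrow(object@runs), sum(object@runs$ok)))
  if (nrow(object@parameters)) {
    agg <- stats::aggregate(cbind(estimate, rel_error, terminal_sd) ~ parameter,
                            data = object@parameters, FUN = mean)
    print(agg)
  }
})

#' Observation-noise sweep
#'
#' Repeats a scenario at increasing observation-noise levels and tabulates
#' the per-parameter recovery statistics, with a monotonicity diagnostic on
#' the estimate SDs (precision is expected to degrade with noise).
#'
#' @param sc a \code{\link{Scenario}} (its noise element supplies
#'   \code{sigmaSys}).
#' @param sigmaObsLevels numeric vector of at least two observation-noise
#'   SDs, in increasing order.
#' @return data.frame with one row per (level, parameter): normalized
#'   discrepancy quartiles, mean terminal SD, chain SD.
#' @export
noiseSweep <- function(sc, sigmaObsLevels) {
  if (length(sigmaObsLevels) < 2)
    stop("need at least two observation-noise levels")
  out <- NULL
  for (s in sigmaObsLevels) {
    sci <- sc
    sci@noise <- noiseSpec(sc@noise@sigmaSys, s, sc@noise@gateNoiseSd)
    sci@name <- sprintf("%s_sobs%g", sc@name, s)
    rep <- runScenario(sci)
    pp <- rep@parameters
    if (!nrow(pp)) next
    agg <- do.call(rbind, lapply(split(pp, pp$parameter), function(g)
      data.frame(sigma_obs = s, parameter = g$parameter[1],
                 nd_q1 = stats::quantile(g$norm_discrepancy, 0.25),
                 nd_med = stats::median(g$norm_discrepancy),
                 nd_q3 = stats::quantile(g$norm_discrepancy, 0.75),
                 sd_mean = mean(g$terminal_sd),
                 est_sd = stats::sd(g$estimate))))
    out <- rbind(out, agg)
  }
  rownames(out) <- NULL
  out
}

#' Predictive check of a fitted single-compartment model
#'
#' Deterministic simulations at the estimated parameters: steady-state
#' voltage per subthreshold step (IV relation), spike frequency per
#' suprathreshold step (IF relation), and spike half-width measured at half
#' the peak-to-baseline amplitude.
#'
#' @param model a single-compartment \code{\link{NeuronModel}}.
#' @param thetaHat named parameter estimates (inside the registry bounds).
#' @param amplitudes current-step amplitudes to probe.
#' @param stepDuration duration of each probe step (ms).
#' @param delta integration step (ms).
#' @return list with data.frames \code{iv} (amplitude, steady-state V),
#'   \code{ifr} (amplitude, spike frequency in Hz) and numeric
#'   \code{halfWidth} (ms, NA when no spikes); a warning is issued when no
#'   step elicits spikes.
#' @export
b4PredictiveCheck <- function(model, thetaHat = NULL,
                              amplitudes = seq(0, 4, by = 0.5),
                              stepDuration = 1000, delta = 0.02) {
  p <- .resolveParams(model, thetaHat)
  desc <- compileModel(model)
  dt <- 5 * delta
  nsamp <- floor(stepDuration / dt)
  iv <- NULL; ifr <- NULL; widths <- numeric()
  for (amp in amplitudes) {
    x0 <- .cppSteadyInit(desc, p[["e_leak"]], as.numeric(p))
    iinjSub <- matrix(amp, (nsamp - 1L) * 5L, 1)
    st <- .cppSimulate(desc, as.numeric(p), x0, iinjSub, delta, 5L, 0,
                       numeric(length(stateLayout(model))))
    v <- st[, 1]
    times <- (seq_along(v) - 1) * dt
    sp <- spikeTimes(v, times)
    # drop onset transients: rate over the second half of the step
    spSteady <- sp[sp > stepDuration / 2]
    if (length(sp) == 0) {
      iv <- rbind(iv, data.frame(amplitude = amp,
                                 v_steady = mean(v[times > 0.8 * stepDuration])))
    } else {
      ifr <- rbind(ifr, data.frame(amplitude = amp,
                                   freq_hz = 1000 * length(spSteady) /
                                     (stepDuration / 2)))
      widths <- c(widths, .spikeHalfWidths(v, times))
    }
  }
  if (is.null(ifr))
    warning("no step elicited spikes; IF table is empty")
  list(iv = iv %||% data.frame(amplitude = numeric(), v_steady = numeric()),
       ifr = ifr %||% data.frame(amplitude = numeric(), freq_hz = numeric()),
       halfWidth = if (length(widths)) stats::median(widths) else NA_real_)
}

# Width of each spike at half its baseline-to-peak amplitude.
.spikeHalfWidths <- function(v, times, threshold = 0) {
  sp <- spikeTimes(v, times, threshold)
  if (!length(sp)) return(numeric())
  base <- stats::quantile(v, 0.1)
  widths <- numeric()
  for (t0 in sp) {
    i0 <- which.min(abs(times - t0))
    iwin <- max(1, i0 - 200):min(length(v), i0 + 400)
    pk <- max(v[iwin])
    half <- base + (pk - base) / 2
    above <- v[iwin] >= half
    runs <- rle(above)
    if (!any(runs$values)) next
    ipk <- which.max(v[iwin])
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1
    j <- which(runs$values & starts <= ipk & ends >= ipk)
    if (length(j) == 1)
      widths <- c(widths, (ends[j] - starts[j] + 1) * (times[2] - times[1]))
  }
  widths
}
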