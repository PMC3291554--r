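#' @include selforg.R
NULL

#' Construct a smoother configuration
#'
#' @param nParticles ensemble size N.
#' @param lag fixed smoothing lag L (observation steps); 0 gives plain
#'   filtering.
#' @param delta integration step (ms).
#' @param k solver substeps per observation interval (the observation
#'   interval is \code{k * delta}).
#' @param resampleThreshold resample when ESS < threshold * N.
#' @param adaptA,adaptB,adaptC adaptation constants of the proposal mean,
#'   covariance and scale factor.
#' @param tauInterval prior interval of the per-particle scale factor.
#' @param jitter relative covariance jitter.
#' @param C0 initial proposal covariance matrix (default identity).
#' @param seed RNG seed.
#' @param maxDegenerate consecutive all-underflow observations tolerated.
#' @param terminalFraction trailing fraction of the run averaged for the
#'   final estimate.
#' @return a \code{\link{SmootherConfig}}.
#' @export
smootherConfig <- function(nParticles = 1000, lag = 100, delta = 0.02, k = 5,
                           resampleThreshold = 0.5, adaptA = 0.1,
                           adaptB = 0.1, adaptC = 0.1,
                           tauInterval = c(0, 0.5), jitter = 1e-12,
                           C0 = NULL, seed = 1, maxDegenerate = 0,
                           terminalFraction = 0.2) {
  new("SmootherConfig", nParticles = as.integer(nParticles),
      lag = as.integer(lag), delta = delta, k = as.integer(k),
      resampleThreshold = resampleThreshold, adaptA = adaptA,
      adaptB = adaptB, adaptC = adaptC, tauInterval = tauInterval,
      jitter = jitter, C0 = C0, seed = as.integer(seed),
      maxDegenerate = as.integer(maxDegenerate),
      terminalFraction = terminalFraction)
}

# Shared driver behind runFixedLagSmoother (G = 1) and fitMultiTrace (G > 1).
.runSmoother <- function(model, recordings, free, config, priorBox = NULL,
                         fixed = NULL) {
  reg <- paramRegistry(model)
  bad <- setdiff(free, reg$name)
  if (length(bad))
    stop("free parameter not in the registry: ", paste(bad, collapse = ", "))
  notFree <- setdiff(free, freeParams(model))
  if (length(notFree))
    stop("parameter(s) flagged fixed in the registry: ",
         paste(notFree, collapse = ", "))

  pbase <- .resolveParams(model, fixed)
  bounds <- paramBounds(model, free)
  if (!is.null(priorBox)) {
    if (is.null(colnames(priorBox))) {
      if (ncol(priorBox) != length(free))
        stop("priorBox must have one column per free parameter")
      colnames(priorBox) <- free
    }
    full <- paramBounds(model, colnames(priorBox))
    if (any(priorBox["lower", ] < full["lower", ] - 1e-9) ||
        any(priorBox["upper", ] > full["upper", ] + 1e-9))
      stop("priorBox must lie inside the registry bounds")
    bounds[, colnames(priorBox)] <- priorBox[c("lower", "upper"), ]
  }

  nc <- length(model@compartments)
  k <- config@k
  recs <- lapply(recordings, function(rec) {
    if (abs(rec@sampleInterval - k * config@delta) > 1e-9)
      stop(sprintf(paste0("recording sample interval (%g ms) must equal ",
                          "k * delta (%g ms)"),
                   rec@sampleInterval, k * config@delta))
    if (any(rec@channelMap > nc))
      stop("recording channels do not map to model compartments")
    nsamp <- nrow(rec@y)
    iinjSub <- rec@iInj[rep(seq_len(nsamp - 1L), each = k), , drop = FALSE]
    list(y = rec@y, chanComp = as.integer(rec@channelMap - 1L),
         iinjSub = iinjSub)
  })
  nobs <- nrow(recs[[1]]$y)

  d <- length(free)
  C0 <- config@C0
  if (is.null(C0)) C0 <- diag(max(d, 1))
  cfg <- list(n_particles = config@nParticles, lag = config@lag,
              delta = config@delta, k = k,
              resample_threshold = config@resampleThreshold,
              a = config@adaptA, b = config@adaptB, c = config@adaptC,
              tau_lo = config@tauInterval[1], tau_hi = config@tauInterval[2],
              jitter = config@jitter, max_degenerate = config@maxDegenerate,
              gate_sd = numeric(length(stateLayout(model))), C0 = C0)

  set.seed(config@seed)
  out <- .cppSmoother(compileModel(model), recs,
                      as.integer(match(free, reg$name) - 1L),
                      bounds["lower", ], bounds["upper", ],
                      as.numeric(pbase), cfg)

  times <- (seq_len(nobs) - 1L) * recordings[[1]]@sampleInterval
  lay <- stateLayout(model)
  G <- length(recordings)
  stateCols <- if (G == 1) lay else
    paste(rep(paste0("trace", seq_len(G)), each = length(lay)), lay, sep = ".")
  colnames(out$smoothed_states) <- stateCols
  colnames(out$theta_mean) <- colnames(out$theta_sd) <- free

  win <- seq.int(max(1L, ceiling(nobs * (1 - config@terminalFraction))), nobs)
  finalEst <- colMeans(out$theta_mean[win, , drop = FALSE])
  finalSd <- apply(out$theta_mean[win, , drop = FALSE], 2, stats::sd)

  new("FitResult", modelName = model@name, freeParams = free, times = times,
      thetaMean = out$theta_mean, thetaSd = out$theta_sd,
      smoothedStates = out$smoothed_states, ess = as.numeric(out$ess),
      tauMean = as.numeric(out$tau_mean), traceC = as.numeric(out$trace_C),
      resampled = as.logical(out$resampled),
      boundHits = as.integer(out$bound_hits),
      finalEstimate = stats::setNames(finalEst, free),
      finalSd = stats::setNames(finalSd, free), nTraces = as.integer(G),
      config = config, priorBox = bounds)
}

#' Run the fixed-lag self-organising smoother on one recording
#'
#' Iterates over observation times: the adaptive parameter-evolution step
#' (scale factors, proposal mean and covariance, parameter resampling), then
#' propagation of the hidden states through the stochastic model dynamics
#' (the proposal is the transition density), Gaussian likelihood weighting
#' of the observed voltage(s), and ESS-triggered systematic resampling of
#' the whole lag-window trajectories.  Initial particles are drawn uniformly
#' from the prior box.
#'
#' @param model a \code{\link{NeuronModel}}.
#' @param recording a \code{\link{Recording}} whose sampling interval equals
#'   \code{k * delta} of the configuration.
#' @param free character vector of free parameter names (subset of
#'   \code{\link{freeParams}}); may be empty for pure state estimation.
#' @param config a \code{\link{SmootherConfig}}.
#' @param priorBox optional bounds matrix (rows \code{lower}, \code{upper})
#'   overriding the registry bounds for (a subset of) the free parameters;
#'   must lie inside the registry bounds.
#' @param fixed named overrides for parameters not being estimated (e.g.
#'   known noise levels).
#' @return a \code{\link{FitResult}}.
#' @examples
#' m <- buildModel("hh1c")
#' p <- generateProtocol(-5, 20, 10, 100, totalT = 100, seed = 2)
#' rec <- simulateRecording(m, p, noiseSpec(0.5, 1), seed = 2)
#' fit <- runFixedLagSmoother(m, rec, free = c("g_na", "g_k"),
#'                            smootherConfig(nParticles = 200, lag = 20,
#'                                           seed = 3))
#' finalEstimate(fit)
#' @export
runFixedLagSmoother <- function(model, recording, free, config,
                                priorBox = NULL, fixed = NULL) {
  .runSmoother(model, list(recording), free, config, priorBox, fixed)
}

## FitResult accessors -------------------------------------------------------

#' @rdname finalEstimate
setMethod("finalEstimate", "FitResult", function(object) object@finalEstimate)

#' @rdname parameterChains
setMethod("parameterChains", "FitResult", function(object) object@thetaMean)

#' @rdname smoothedStates
setMethod("smoothedStates", "FitResult", function(object)
  object@smoothedStates)

#' @rdname essTrace
setMethod("essTrace", "FitResult", function(object) object@ess)

#' @rdname sampleTimes
setMethod("sampleTimes", "FitResult", function(object) object@times)

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult: model '%s', %d observations, %d trace(s), %d free parameter(s)\n",
              object@modelName, length(object@times), object@nTraces,
              length(object@freeParams)))
  cat(sprintf("  N = %d, lag = %d, resampled %d times, min ESS = %.1f\n",
              object@config@nParticles, object@config@lag,
              sum(object@resampled), min(object@ess)))
  if (length(object@freeParams)) {
    est <- data.frame(estimate = signif(object@finalEstimate, 4),
                      sd = signif(object@finalSd, 4))
    print(est)
  }
})

#' Write a fit result to delimited text files
#'
#' Writes \code{<stem>_chains.csv} (per-time parameter expectations and SDs,
#' ESS, adaptation diagnostics) and \code{<stem>_summary.yaml} (final
#' estimates, prior box, configuration echo).
#'
#' @param fit a \code{\link{FitResult}}.
#' @param stem output path stem.
#' @return the two paths, invisibly.
#' @export
writeFitResult <- function(fit, stem) {
  chains <- data.frame(time_ms = fit@times, fit@thetaMean,
                       check.names = FALSE)
  if (length(fit@freeParams))
    colnames(chains)[-1] <- fit@freeParams
  sdcols <- fit@thetaSd
  if (length(fit@freeParams))
    colnames(sdcols) <- paste0("sd_", fit@freeParams)
  chains <- cbind(chains, sdcols, ess = fit@ess, tau_mean = fit@tauMean,
                  trace_C = fit@traceC, resampled = as.integer(fit@resampled))
  f1 <- paste0(stem, "_chains.csv")
  utils::write.csv(chains, f1, row.names = FALSE)
  cfg <- fit@config
  summary <- list(
    model = fit@modelName,
    free_parameters = as.list(fit@freeParams),
    final_estimate = as.list(fit@finalEstimate),
    final_sd = as.list(fit@finalSd),
    bound_hits = as.list(stats::setNames(fit@boundHits, fit@freeParams)),
    prior_lower = as.list(fit@priorBox["lower", ]),
    prior_upper = as.list(fit@priorBox["upper", ]),
    n_traces = fit@nTraces,
    config = list(n_particles = cfg@nParticles, lag = cfg@lag,
                  delta = cfg@delta, k = cfg@k,
                  resample_threshold = cfg@resampleThreshold,
                  a = cfg@adaptA, b = cfg@adaptB, c = cfg@adaptC,
                  tau_interval = as.list(cfg@tauInterval), seed = cfg@seed))
  f2 <- paste0(stem, "_summary.yaml")
  writeLines(yaml::as.yaml(summary), f2)
  invisible(c(f1, f2))
}
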