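#' @include AllClasses.R
NULL

#' Steady-state open fraction of a gate
#'
#' @param gate a \code{\link{GateKinetics}}.
#' @param v membrane potential (mV), finite; vectorised.
#' @return open fraction in (0, 1), monotone in \code{v} with the sign of
#'   the gate's slope.
#' @export
setGeneric("steadyState", function(gate, v) standardGeneric("steadyState"))

#' Relaxation time of a gate
#'
#' @param gate a \code{\link{GateKinetics}}.
#' @param v membrane potential (mV), finite; vectorised.
#' @return relaxation time (ms), strictly positive.  In voltage-dependent
#'   mode the curve is a symmetric bell with maximum \code{base + amplitude}
#'   at its center, decaying to the base level far from it.
#' @export
setGeneric("relaxationTime", function(gate, v) standardGeneric("relaxationTime"))

#' Parameter registry of a model
#' @param object a \code{\link{NeuronModel}}.
#' @return data.frame with columns name, unit, value, lower, upper, free.
#' @export
setGeneric("paramRegistry", function(object) standardGeneric("paramRegistry"))

#' State layout of a model
#' @param object a \code{\link{NeuronModel}}.
#' @return ordered character vector of dynamic state names.
#' @export
setGeneric("stateLayout", function(object) standardGeneric("stateLayout"))

#' Names of the estimable (free) parameters
#' @param object a \code{\link{NeuronModel}}.
#' @export
setGeneric("freeParams", function(object) standardGeneric("freeParams"))

#' Default parameter values as a named vector
#' @param object a \code{\link{NeuronModel}}.
#' @export
setGeneric("paramDefaults", function(object) standardGeneric("paramDefaults"))

#' Prior bounds of parameters
#' @param object a \code{\link{NeuronModel}}.
#' @param which optional character vector of parameter names.
#' @return matrix with rows \code{lower} and \code{upper}.
#' @export
setGeneric("paramBounds", function(object, which = NULL)
  standardGeneric("paramBounds"))

#' Observation times of a recording or fit
#' @param object a \code{\link{Recording}} or \code{\link{FitResult}}.
#' @export
setGeneric("sampleTimes", function(object) standardGeneric("sampleTimes"))

#' Observed voltage matrix
#' @param object a \code{\link{Recording}}.
#' @export
setGeneric("observedVoltage", function(object)
  standardGeneric("observedVoltage"))

#' Injected current matrix
#' @param object a \code{\link{Recording}}.
#' @export
setGeneric("injectedCurrent", function(object)
  standardGeneric("injectedCurrent"))

#' True hidden-state trajectories of a synthetic recording
#' @param object a \code{\link{Recording}}.
#' @export
setGeneric("hiddenStates", function(object) standardGeneric("hiddenStates"))

#' Terminal-window parameter estimate of a fit
#' @param object a \code{\link{FitResult}}.
#' @export
setGeneric("finalEstimate", function(object) standardGeneric("finalEstimate"))

#' Per-time posterior means of the free parameters
#' @param object a \code{\link{FitResult}}.
#' @export
setGeneric("parameterChains", function(object)
  standardGeneric("parameterChains"))

#' Fixed-lag smoothed hidden-state expectations
#' @param object a \code{\link{FitResult}}.
#' @export
setGeneric("smoothedStates", function(object) standardGeneric("smoothedStates"))

#' Effective-sample-size trace
#' @param object a \code{\link{FitResult}}.
#' @export
setGeneric("essTrace", function(object) standardGeneric("essTrace"))
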