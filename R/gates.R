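#' @include AllGenerics.R
NULL

#' Construct gate kinetics
#'
#' @param name gate label.
#' @param vHalf half-activation voltage (mV).
#' @param slope sigmoid slope (mV, signed; positive = activation-like).
#' @param tau either a single positive number (constant relaxation time, ms)
#'   or a numeric of length 4 \code{c(base, amplitude, center, width)} for
#'   the voltage-dependent bell.
#' @return a \code{\link{GateKinetics}}.
#' @examples
#' m <- gateKinetics("m", vHalf = -40, slope = 7.5, tau = c(0.1, 0.4, -40, 30))
#' steadyState(m, -40)          # 0.5 at the half-activation voltage
#' relaxationTime(m, -40)       # base + amplitude at the curve center
#' @export
gateKinetics <- function(name, vHalf, slope, tau = 1) {
  if (length(tau) == 1) {
    new("GateKinetics", name = name, vHalf = vHalf, slope = slope,
        tauMode = "constant", tauConst = tau)
  } else {
    stopifnot(length(tau) == 4)
    tau <- as.numeric(tau)
    names(tau) <- c("base", "amplitude", "center", "width")
    new("GateKinetics", name = name, vHalf = vHalf, slope = slope,
        tauMode = "voltage_dependent", tauConst = tau[["base"]],
        tauParams = tau)
  }
}

#' @rdname steadyState
setMethod("steadyState", "GateKinetics", function(gate, v) {
  if (!all(is.finite(v))) stop("membrane potential must be finite")
  1 / (1 + exp(-(v - gate@vHalf) / gate@slope))
})

#' @rdname relaxationTime
setMethod("relaxationTime", "GateKinetics", function(gate, v) {
  if (!all(is.finite(v))) stop("membrane potential must be finite")
  if (gate@tauMode == "constant") {
    rep_len(gate@tauConst, length(v))
  } else {
    tp <- gate@tauParams
    tp[["base"]] + tp[["amplitude"]] / cosh((v - tp[["center"]]) / tp[["width"]])
  }
})

setMethod("show", "GateKinetics", function(object) {
  tau <- if (object@tauMode == "constant")
    sprintf("tau = %g ms", object@tauConst)
  else
    sprintf("tau(V) = %g + %g/cosh((V - %g)/%g) ms",
            object@tauParams[["base"]], object@tauParams[["amplitude"]],
            object@tauParams[["center"]], object@tauParams[["width"]])
  cat(sprintf("gate '%s': x_inf(V) = 1/(1 + exp(-(V - %g)/%g)), %s\n",
              object@name, object@vHalf, object@slope, tau))
})

#' Construct an ionic-current specification
#'
#' @param name current label; conductance is registered as \code{g_<name>}.
#' @param gMax maximal conductance.
#' @param eRev reversal potential (mV).
#' @param eRevName registry name for the reversal potential; defaults to
#'   \code{e_<name>}.  Currents carried by the same ion should share it.
#' @param actGate activation \code{\link{GateKinetics}} or \code{NULL}.
#' @param actPower integer exponent of the activation gate (1..4).
#' @param inactGate inactivation \code{\link{GateKinetics}} or \code{NULL}.
#' @param inactPower integer exponent of the inactivation gate.
#' @param actMode \code{"dynamic"} or \code{"instantaneous"}; an
#'   instantaneous activation gate is evaluated at its voltage-dependent
#'   steady state and contributes no dynamic state.
#' @param caModulation half-saturation constant Kd for calcium-activated
#'   conductances, or \code{NA}.
#' @param carriesCalcium \code{TRUE} for calcium currents that feed the
#'   compartment's calcium pool.
#' @return an \code{\link{IonCurrentSpec}}.
#' @export
ionCurrent <- function(name, gMax, eRev, eRevName = paste0("e_", name),
                       actGate = NULL, actPower = 1L, inactGate = NULL,
                       inactPower = 1L, actMode = "dynamic",
                       caModulation = NA_real_, carriesCalcium = FALSE) {
  new("IonCurrentSpec", name = name, eRevName = eRevName, gMax = gMax,
      eRev = eRev, actGate = actGate, actPower = as.integer(actPower),
      inactGate = inactGate, inactPower = as.integer(inactPower),
      actMode = actMode, caModulation = caModulation,
      carriesCalcium = carriesCalcium)
}

#' Evaluate an ionic current
#'
#' Computes \eqn{I = \bar g\, x^p\, y^q\, f_{Ca}\, (V - E)} with \eqn{f_{Ca}
#' = [\mathrm{Ca}]/([\mathrm{Ca}] + K_d)} when the current is
#' calcium-activated.  Dynamic gate values must be supplied in \code{gates};
#' instantaneous activation is evaluated from the gate's steady state.
#'
#' @param spec an \code{\link{IonCurrentSpec}}.
#' @param v membrane potential (mV).
#' @param gates named numeric of gate values in [0, 1].
#' @param ca calcium concentration (needed only for calcium-activated
#'   currents).
#' @return current in the model's unit system.
#' @export
ionicCurrent <- function(spec, v, gates = numeric(), ca = NA_real_) {
  open <- 1
  if (!is.null(spec@actGate)) {
    if (spec@actMode == "instantaneous") {
      xv <- steadyState(spec@actGate, v)
    } else {
      gn <- spec@actGate@name
      if (!gn %in% names(gates))
        stop(sprintf("missing value for dynamic gate '%s'", gn))
      xv <- gates[[gn]]
      if (xv < 0 || xv > 1) stop("gate values must lie in [0, 1]")
    }
    open <- open * xv^spec@actPower
  }
  if (!is.null(spec@inactGate)) {
    gn <- spec@inactGate@name
    if (!gn %in% names(gates))
      stop(sprintf("missing value for dynamic gate '%s'", gn))
    yv <- gates[[gn]]
    if (yv < 0 || yv > 1) stop("gate values must lie in [0, 1]")
    open <- open * yv^spec@inactPower
  }
  if (!is.na(spec@caModulation)) {
    if (is.na(ca)) stop("calcium concentration required for a calcium-activated current")
    open <- open * ca / (ca + spec@caModulation)
  }
  spec@gMax * open * (v - spec@eRev)
}
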