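#' @include gates.R
NULL

#' Construct a compartment
#'
#' @param name compartment label.
#' @param cM membrane capacitance.
#' @param gLeak,eLeak leak conductance and reversal potential.
#' @param currents list of \code{\link{IonCurrentSpec}}.
#' @param caParams named numeric \code{c(alpha=, removal=)} to attach a
#'   first-order calcium pool, or \code{NULL}.
#' @return a \code{\link{CompartmentSpec}}.
#' @export
compartment <- function(name, cM, gLeak, eLeak, currents = list(),
                        caParams = NULL) {
  has_ca <- !is.null(caParams)
  if (!has_ca) caParams <- c(alpha = 0, removal = 1)
  new("CompartmentSpec", name = name, cM = cM, gLeak = gLeak, eLeak = eLeak,
      currents = currents, hasCalcium = has_ca, caParams = caParams)
}

## ---------------------------------------------------------------------------
## Registry assembly: walk the structure and derive one row per parameter.
## The registry (not the structural objects) is what evaluation reads.
## ---------------------------------------------------------------------------

.regRow <- function(name, unit, value, lower, upper, free = TRUE,
                    narrow = c(NA_real_, NA_real_)) {
  data.frame(name = name, unit = unit, value = value, lower = lower,
             upper = upper, free = free, narrowLower = narrow[1],
             narrowUpper = narrow[2], stringsAsFactors = FALSE)
}

.gateParamNames <- function(gate) {
  g <- gate@name
  if (gate@tauMode == "constant")
    c(vhalf = paste0(g, "_vhalf"), slope = paste0(g, "_slope"),
      tau = paste0(g, "_tau"))
  else
    c(vhalf = paste0(g, "_vhalf"), slope = paste0(g, "_slope"),
      tau_base = paste0(g, "_tau_base"), tau_amp = paste0(g, "_tau_amp"),
      tau_center = paste0(g, "_tau_center"), tau_width = paste0(g, "_tau_width"))
}

# Collect default values implied by the structure, used to cross-check the
# registry a builder declares.
.structureDefaults <- function(compartments, couplingG, somaAreaRatio) {
  vals <- list()
  put <- function(nm, v) {
    if (!is.null(vals[[nm]]) && abs(vals[[nm]] - v) > 1e-12)
      stop(sprintf("conflicting defaults for parameter '%s'", nm))
    vals[[nm]] <<- v
  }
  for (cp in compartments) {
    put("cm", cp@cM)
    put("g_leak", cp@gLeak)
    put("e_leak", cp@eLeak)
    if (cp@hasCalcium) {
      put("ca_alpha", cp@caParams[["alpha"]])
      put("ca_k", cp@caParams[["removal"]])
    }
    for (cur in cp@currents) {
      put(paste0("g_", cur@name), cur@gMax)
      put(cur@eRevName, cur@eRev)
      if (!is.na(cur@caModulation)) put(paste0("kd_", cur@name), cur@caModulation)
      for (gate in Filter(Negate(is.null), list(cur@actGate, cur@inactGate))) {
        nm <- .gateParamNames(gate)
        put(nm[["vhalf"]], gate@vHalf)
        put(nm[["slope"]], gate@slope)
        if (gate@tauMode == "constant") put(nm[["tau"]], gate@tauConst)
        else {
          put(nm[["tau_base"]], gate@tauParams[["base"]])
          put(nm[["tau_amp"]], gate@tauParams[["amplitude"]])
          put(nm[["tau_center"]], gate@tauParams[["center"]])
          put(nm[["tau_width"]], gate@tauParams[["width"]])
        }
      }
    }
  }
  if (length(compartments) > 1) {
    put("g_c", couplingG)
    put("rho", somaAreaRatio)
  }
  vals
}

# Derive the state layout: one voltage per compartment, then dynamic gates in
# walk order, then calcium pools.  Instantaneous gates contribute no state.
.deriveStateLayout <- function(compartments) {
  nc <- length(compartments)
  suffix <- if (nc > 1) paste0("_", substr(vapply(compartments, slot,
                                                  "", "name"), 1, 1))
            else ""
  v_names <- if (nc == 1) "v" else paste0("v", suffix)
  gate_entries <- list() # name -> list(comp, gate, stateName)
  for (ci in seq_along(compartments)) {
    for (cur in compartments[[ci]]@currents) {
      gs <- list()
      if (!is.null(cur@actGate) && cur@actMode == "dynamic")
        gs <- c(gs, list(cur@actGate))
      if (!is.null(cur@inactGate)) gs <- c(gs, list(cur@inactGate))
      for (gate in gs) {
        key <- paste0(gate@name, "@", ci)
        if (is.null(gate_entries[[key]]))
          gate_entries[[key]] <- list(comp = ci, gate = gate)
      }
    }
  }
  gate_names <- vapply(gate_entries, function(e) e$gate@name, "")
  dup <- gate_names %in% gate_names[duplicated(gate_names)]
  state_names <- ifelse(dup & nc > 1,
    paste0(gate_names, suffix[vapply(gate_entries, `[[`, 1L, "comp")]),
    gate_names)
  ca_names <- character()
  ca_comp <- integer()
  for (ci in seq_along(compartments)) {
    if (compartments[[ci]]@hasCalcium) {
      ca_names <- c(ca_names, if (nc == 1) "ca" else paste0("ca", suffix[ci]))
      ca_comp <- c(ca_comp, ci)
    }
  }
  list(layout = c(v_names, unname(state_names), ca_names),
       gateEntries = gate_entries, gateStateNames = unname(state_names),
       caComp = ca_comp)
}

.newNeuronModel <- function(name, compartments, couplingG, somaAreaRatio,
                            registry) {
  lay <- .deriveStateLayout(compartments)
  vals <- .structureDefaults(compartments, couplingG, somaAreaRatio)
  for (nm in names(vals)) {
    i <- match(nm, registry$name)
    if (is.na(i))
      stop(sprintf("registry is missing parameter '%s' implied by the structure", nm))
    if (abs(registry$value[i] - vals[[nm]]) > 1e-12)
      stop(sprintf("registry default for '%s' disagrees with the structure", nm))
  }
  new("NeuronModel", name = name, compartments = compartments,
      couplingG = couplingG, somaAreaRatio = somaAreaRatio,
      stateLayout = lay$layout, paramRegistry = registry)
}

## ---------------------------------------------------------------------------
## Accessors
## ---------------------------------------------------------------------------

#' @rdname paramRegistry
setMethod("paramRegistry", "NeuronModel", function(object) object@paramRegistry)

#' @rdname stateLayout
setMethod("stateLayout", "NeuronModel", function(object) object@stateLayout)

#' @rdname freeParams
setMethod("freeParams", "NeuronModel", function(object)
  object@paramRegistry$name[object@paramRegistry$free])

#' @rdname paramDefaults
setMethod("paramDefaults", "NeuronModel", function(object) {
  stats::setNames(object@paramRegistry$value, object@paramRegistry$name)
})

#' @rdname paramBounds
setMethod("paramBounds", "NeuronModel", function(object, which = NULL) {
  reg <- object@paramRegistry
  if (is.null(which)) which <- reg$name
  i <- match(which, reg$name)
  if (anyNA(i)) stop("unknown parameter: ", paste(which[is.na(i)], collapse = ", "))
  b <- rbind(lower = reg$lower[i], upper = reg$upper[i])
  colnames(b) <- which
  b
})

#' Narrow prior intervals of a model
#'
#' Some kinetic parameters carry a second, narrower prior interval used in
#' the informative-prior experiments.  Returns the registry bounds with the
#' narrow interval substituted where one is defined.
#'
#' @param model a \code{\link{NeuronModel}}.
#' @return matrix with rows \code{lower}, \code{upper}, columns all
#'   parameters.
#' @export
narrowBounds <- function(model) {
  reg <- model@paramRegistry
  lo <- ifelse(is.na(reg$narrowLower), reg$lower, reg$narrowLower)
  hi <- ifelse(is.na(reg$narrowUpper), reg$upper, reg$narrowUpper)
  m <- rbind(lower = lo, upper = hi)
  colnames(m) <- reg$name
  m
}

setMethod("show", "NeuronModel", function(object) {
  cat(sprintf("NeuronModel '%s': %d compartment(s), %d states, %d parameters (%d free)\n",
              object@name, length(object@compartments),
              length(object@stateLayout), nrow(object@paramRegistry),
              sum(object@paramRegistry$free)))
  cat("  states:", paste(object@stateLayout, collapse = ", "), "\n")
  for (cp in object@compartments)
    cat(sprintf("  %s: leak + %s\n", cp@name,
                paste(vapply(cp@currents, slot, "", "name"), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## Compilation to the numeric descriptor used by the compiled core
## ---------------------------------------------------------------------------

#' Compile a model to its evaluation descriptor
#'
#' Internal: translates the declarative structure into parameter-index
#' tables used by the compiled drift/simulation/smoother routines.
#'
#' @param model a \code{\link{NeuronModel}}.
#' @return a list descriptor (indices are 0-based).
#' @keywords internal
compileModel <- function(model) {
  reg <- model@paramRegistry
  idx <- function(nm) {
    i <- match(nm, reg$name)
    if (anyNA(i)) stop("unknown registry parameter: ", nm[is.na(i)][1])
    i - 1L
  }
  comps <- model@compartments
  nc <- length(comps)
  lay <- .deriveStateLayout(comps)
  state_idx <- stats::setNames(seq_along(lay$layout) - 1L, lay$layout)

  gate_keys <- names(lay$gateEntries)
  gate_rows <- matrix(-1L, nrow = length(gate_keys), ncol = 10)
  for (j in seq_along(gate_keys)) {
    e <- lay$gateEntries[[j]]
    g <- e$gate
    nm <- .gateParamNames(g)
    row <- c(state_idx[[lay$gateStateNames[j]]], e$comp - 1L,
             idx(nm[["vhalf"]]), idx(nm[["slope"]]),
             if (g@tauMode == "constant") c(0L, idx(nm[["tau"]]), -1L, -1L, -1L, -1L)
             else c(1L, -1L, idx(nm[["tau_base"]]), idx(nm[["tau_amp"]]),
                    idx(nm[["tau_center"]]), idx(nm[["tau_width"]])))
    gate_rows[j, ] <- as.integer(row)
  }

  cur_rows <- NULL
  for (ci in seq_len(nc)) {
    cp <- comps[[ci]]
    # leak as a gateless current
    cur_rows <- rbind(cur_rows, c(ci - 1L, idx("g_leak"), idx("e_leak"),
                                  0L, -1L, -1L, -1L, 1L, -1L, 1L, -1L, 0L))
    for (cur in cp@currents) {
      act_type <- 0L; act_gate <- -1L; act_vh <- -1L; act_sl <- -1L
      if (!is.null(cur@actGate)) {
        nm <- .gateParamNames(cur@actGate)
        if (cur@actMode == "dynamic") {
          act_type <- 1L
          act_gate <- match(paste0(cur@actGate@name, "@", ci), gate_keys) - 1L
        } else {
          act_type <- 2L
          act_vh <- idx(nm[["vhalf"]]); act_sl <- idx(nm[["slope"]])
        }
      }
      inact_gate <- -1L
      if (!is.null(cur@inactGate))
        inact_gate <- match(paste0(cur@inactGate@name, "@", ci), gate_keys) - 1L
      kd <- if (is.na(cur@caModulation)) -1L else idx(paste0("kd_", cur@name))
      cur_rows <- rbind(cur_rows,
        c(ci - 1L, idx(paste0("g_", cur@name)), idx(cur@eRevName),
          act_type, act_gate, act_vh, act_sl, cur@actPower,
          inact_gate, cur@inactPower, kd, as.integer(cur@carriesCalcium)))
    }
  }
  storage.mode(cur_rows) <- "integer"

  ca_rows <- matrix(integer(), 0, 4)
  if (length(lay$caComp)) {
    ca_names <- lay$layout[grepl("^ca", lay$layout)]
    ca_rows <- cbind(lay$caComp - 1L, state_idx[ca_names],
                     rep(idx("ca_alpha"), length(lay$caComp)),
                     rep(idx("ca_k"), length(lay$caComp)))
    storage.mode(ca_rows) <- "integer"
  }

  list(ncomp = nc, nstate = length(lay$layout),
       cm = rep(idx("cm"), nc),
       gc_idx = if (nc > 1) idx("g_c") else -1L,
       rho_idx = if (nc > 1) idx("rho") else -1L,
       sigma_sys_idx = idx("sigma_sys"), sigma_obs_idx = idx("sigma_obs"),
       gates = gate_rows, currents = cur_rows, ca = ca_rows)
}

# Resolve a full parameter vector from registry defaults plus named overrides.
.resolveParams <- function(model, overrides = NULL, checkBounds = TRUE) {
  p <- paramDefaults(model)
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad))
      stop("unknown parameter name in overrides: ", paste(bad, collapse = ", "))
    if (checkBounds) {
      b <- paramBounds(model, names(overrides))
      out <- overrides < b["lower", ] | overrides > b["upper", ]
      if (any(out))
        stop("override outside registry bounds: ",
             paste(names(overrides)[out], collapse = ", "))
    }
    p[names(overrides)] <- overrides
  }
  p
}

#' Drift (deterministic time derivative) of a model state
#'
#' Evaluates the right-hand side of the model's ODE system: current
#' conservation for each compartment voltage (including the soma-dendrite
#' coupling term for two-compartment models), first-order gate relaxation,
#' and linear calcium-pool dynamics.  Instantaneous-activation currents use
#' the activation steady state at the present voltage.
#'
#' @param model a \code{\link{NeuronModel}}.
#' @param x state vector in the model's \code{\link{stateLayout}} order.
#' @param iInj injected current, one value per compartment.
#' @param overrides named numeric of parameter overrides (must be inside the
#'   registry bounds).
#' @return named numeric: dx/dt.
#' @examples
#' m <- buildModel("hh1c")
#' x0 <- initialState(m, v0 = -60)
#' drift(m, x0, iInj = 0)
#' @export
drift <- function(model, x, iInj, overrides = NULL) {
  p <- .resolveParams(model, overrides)
  nc <- length(model@compartments)
  if (length(iInj) != nc)
    stop(sprintf("iInj must supply %d compartment current(s)", nc))
  if (length(x) != length(model@stateLayout))
    stop("state vector length does not match the state layout")
  out <- .cppDrift(compileModel(model), as.numeric(x), as.numeric(iInj),
                   as.numeric(p))
  stats::setNames(out, model@stateLayout)
}

#' Initial state at a holding potential
#'
#' Voltages set to \code{v0}, gates at their steady state, calcium pools at
#' the equilibrium of their removal dynamics.
#'
#' @param model a \code{\link{NeuronModel}}.
#' @param v0 holding potential (mV), recycled across compartments.
#' @param overrides named parameter overrides.
#' @return named state vector.
#' @export
initialState <- function(model, v0, overrides = NULL) {
  p <- .resolveParams(model, overrides)
  nc <- length(model@compartments)
  v0 <- rep_len(v0, nc)
  stats::setNames(
    .cppSteadyInit(compileModel(model), as.numeric(v0), as.numeric(p)),
    model@stateLayout)
}

## ---------------------------------------------------------------------------
## The three built-in model families
## ---------------------------------------------------------------------------

.build_hh1c <- function() {
  m <- gateKinetics("m", vHalf = -40, slope = 7.5, tau = c(0.1, 0.4, -40, 30))
  h <- gateKinetics("h", vHalf = -60, slope = -7.5, tau = c(1.2, 7.4, -62, 20))
  n <- gateKinetics("n", vHalf = -50, slope = 15, tau = c(1.1, 4.7, -65, 50))
  soma <- compartment("soma", cM = 1, gLeak = 0.3, eLeak = -60, currents = list(
    ionCurrent("na", gMax = 120, eRev = 40, actGate = m, actPower = 3,
               inactGate = h),
    ionCurrent("k", gMax = 36, eRev = -80, actGate = n, actPower = 4)))
  reg <- rbind(
    .regRow("g_na",  "mS/cm2", 120, 0, 250),
    .regRow("g_k",   "mS/cm2", 36, 0, 100),
    .regRow("g_leak","mS/cm2", 0.3, 0, 2),
    .regRow("e_na",  "mV", 40, 0, 100),
    .regRow("e_k",   "mV", -80, -100, -50),
    .regRow("e_leak","mV", -60, -90, -30),
    .regRow("m_vhalf", "mV", -40, -60, -20, narrow = c(-45, -35)),
    .regRow("m_slope", "mV", 7.5, 1, 20, narrow = c(5, 10)),
    .regRow("m_tau_base", "ms", 0.1, 0.02, 1),
    .regRow("m_tau_amp",  "ms", 0.4, 0, 2),
    .regRow("m_tau_width","mV", 30, 5, 60),
    .regRow("h_vhalf", "mV", -60, -80, -40, narrow = c(-65, -55)),
    .regRow("h_slope", "mV", -7.5, -20, -1, narrow = c(-10, -5)),
    .regRow("h_tau_base", "ms", 1.2, 0.1, 5),
    .regRow("h_tau_amp",  "ms", 7.4, 0, 20),
    .regRow("h_tau_width","mV", 20, 5, 60),
    .regRow("n_vhalf", "mV", -50, -70, -30, narrow = c(-55, -45)),
    .regRow("n_slope", "mV", 15, 1, 30, narrow = c(10, 20)),
    .regRow("n_tau_base", "ms", 1.1, 0.1, 5),
    .regRow("n_tau_amp",  "ms", 4.7, 0, 20),
    .regRow("n_tau_width","mV", 50, 5, 80),
    .regRow("sigma_sys", "mV/sqrt(ms)", 0.5, 0, 2),
    .regRow("sigma_obs", "mV", 1, 0.05, 10),
    .regRow("cm", "uF/cm2", 1, 0.5, 2, free = FALSE),
    .regRow("m_tau_center", "mV", -40, -80, 0, free = FALSE),
    .regRow("h_tau_center", "mV", -62, -100, 0, free = FALSE),
    .regRow("n_tau_center", "mV", -65, -100, 0, free = FALSE))
  .newNeuronModel("hh1c", list(soma), couplingG = 0, somaAreaRatio = 1, reg)
}

.build_motoneuron2c <- function() {
  m  <- gateKinetics("m",  vHalf = -35, slope = 7.5,
                     tau = c(0.1, 0.4, -35, 30))       # instantaneous anyway
  h  <- gateKinetics("h",  vHalf = -55, slope = -7.5, tau = c(1, 25, -55, 15))
  n  <- gateKinetics("n",  vHalf = -30, slope = 15, tau = c(1, 6, -45, 25))
  mn <- gateKinetics("mn", vHalf = -30, slope = 5.5, tau = 4)
  hn <- gateKinetics("hn", vHalf = -45, slope = -5.5, tau = 40)
  ml <- gateKinetics("ml", vHalf = -40, slope = 7.5, tau = 40)
  soma <- compartment("soma", cM = 1, gLeak = 0.51, eLeak = -60,
    caParams = c(alpha = 0.002, removal = 0.04), currents = list(
      ionCurrent("na", gMax = 120, eRev = 55, actGate = m, actPower = 3,
                 inactGate = h, actMode = "instantaneous"),
      ionCurrent("k", gMax = 100, eRev = -80, eRevName = "e_k", actGate = n,
                 actPower = 4),
      ionCurrent("can_s", gMax = 14, eRev = 80, eRevName = "e_ca",
                 actGate = mn, actPower = 2, inactGate = hn,
                 carriesCalcium = TRUE),
      ionCurrent("kca_s", gMax = 2, eRev = -80, eRevName = "e_k",
                 caModulation = 0.2)))
  dend <- compartment("dend", cM = 1, gLeak = 0.51, eLeak = -60,
    caParams = c(alpha = 0.002, removal = 0.04), currents = list(
      ionCurrent("can_d", gMax = 0.3, eRev = 80, eRevName = "e_ca",
                 actGate = mn, actPower = 2, inactGate = hn,
                 carriesCalcium = TRUE),
      ionCurrent("cal_d", gMax = 0.33, eRev = 80, eRevName = "e_ca",
                 actGate = ml, actPower = 1, carriesCalcium = TRUE),
      ionCurrent("kca_d", gMax = 1.1, eRev = -80, eRevName = "e_k",
                 caModulation = 0.2)))
  reg <- rbind(
    .regRow("g_na",   "mS/cm2", 120, 0, 250),
    .regRow("g_k",    "mS/cm2", 100, 0, 200),
    .regRow("g_can_s","mS/cm2", 14, 0, 40),
    .regRow("g_kca_s","mS/cm2", 2, 0, 20),
    .regRow("g_can_d","mS/cm2", 0.3, 0, 5),
    .regRow("g_cal_d","mS/cm2", 0.33, 0, 5),
    .regRow("g_kca_d","mS/cm2", 1.1, 0, 10),
    .regRow("e_na", "mV", 55, 0, 100),
    .regRow("e_k",  "mV", -80, -100, -50),
    .regRow("e_ca", "mV", 80, 40, 120),
    .regRow("m_vhalf",  "mV", -35, -60, -10, narrow = c(-45, -25)),
    .regRow("m_slope",  "mV", 7.5, 1, 20, narrow = c(5, 10)),
    .regRow("h_vhalf",  "mV", -55, -80, -30, narrow = c(-65, -45)),
    .regRow("h_slope",  "mV", -7.5, -20, -1, narrow = c(-10, -5)),
    .regRow("n_vhalf",  "mV", -30, -60, 0, narrow = c(-40, -20)),
    .regRow("n_slope",  "mV", 15, 1, 30, narrow = c(10, 20)),
    .regRow("mn_vhalf", "mV", -30, -60, 0, narrow = c(-40, -20)),
    .regRow("mn_slope", "mV", 5.5, 1, 15, narrow = c(3, 8)),
    .regRow("hn_vhalf", "mV", -45, -70, -20, narrow = c(-55, -35)),
    .regRow("hn_slope", "mV", -5.5, -15, -1, narrow = c(-8, -3)),
    .regRow("ml_vhalf", "mV", -40, -70, -10, narrow = c(-50, -30)),
    .regRow("ml_slope", "mV", 7.5, 1, 20, narrow = c(5, 10)),
    .regRow("h_tau_amp", "ms", 25, 0, 60),
    .regRow("n_tau_amp", "ms", 6, 0, 30),
    .regRow("mn_tau", "ms", 4, 0.5, 20),
    .regRow("hn_tau", "ms", 40, 5, 120),
    .regRow("ml_tau", "ms", 40, 5, 120),
    .regRow("g_c",  "mS/cm2", 0.1, 0.01, 1),
    .regRow("rho",  "-", 0.1, 0.05, 0.5),
    .regRow("sigma_sys", "mV/sqrt(ms)", 0.5, 0, 2),
    .regRow("sigma_obs", "mV", 1, 0.05, 10),
    .regRow("g_leak", "mS/cm2", 0.51, 0, 2, free = FALSE),
    .regRow("e_leak", "mV", -60, -90, -30, free = FALSE),
    .regRow("cm", "uF/cm2", 1, 0.5, 2, free = FALSE),
    .regRow("m_tau_base", "ms", 0.1, 0.02, 1, free = FALSE),
    .regRow("m_tau_amp", "ms", 0.4, 0, 2, free = FALSE),
    .regRow("m_tau_center", "mV", -35, -80, 0, free = FALSE),
    .regRow("m_tau_width", "mV", 30, 5, 60, free = FALSE),
    .regRow("h_tau_base", "ms", 1, 0.1, 5, free = FALSE),
    .regRow("h_tau_center", "mV", -55, -100, 0, free = FALSE),
    .regRow("h_tau_width", "mV", 15, 5, 60, free = FALSE),
    .regRow("n_tau_base", "ms", 1, 0.1, 5, free = FALSE),
    .regRow("n_tau_center", "mV", -45, -100, 0, free = FALSE),
    .regRow("n_tau_width", "mV", 25, 5, 60, free = FALSE),
    .regRow("kd_kca_s", "uM", 0.2, 0.01, 2, free = FALSE),
    .regRow("kd_kca_d", "uM", 0.2, 0.01, 2, free = FALSE),
    .regRow("ca_alpha", "uM cm2/(ms uA)", 0.002, 1e-4, 1, free = FALSE),
    .regRow("ca_k", "1/ms", 0.04, 1e-3, 1, free = FALSE))
  .newNeuronModel("motoneuron2c", list(soma, dend), couplingG = 0.1,
                  somaAreaRatio = 0.1, reg)
}

.build_b4 <- function() {
  m <- gateKinetics("m", vHalf = -35, slope = 7.5, tau = 1)  # instantaneous
  h <- gateKinetics("h", vHalf = -55, slope = -7.5, tau = 20)
  n <- gateKinetics("n", vHalf = -25, slope = 12.5, tau = 15)
  a <- gateKinetics("a", vHalf = -30, slope = 7.5, tau = 30)
  b <- gateKinetics("b", vHalf = -10, slope = -20, tau = 47.5)
  soma <- compartment("soma", cM = 1, gLeak = 0.1, eLeak = -60,
    currents = list(
      ionCurrent("na", gMax = 15, eRev = 40, actGate = m, actPower = 3,
                 inactGate = h, actMode = "instantaneous"),
      ionCurrent("k", gMax = 3, eRev = -70, eRevName = "e_k", actGate = n,
                 actPower = 2),
      ionCurrent("a", gMax = 0.5, eRev = -70, eRevName = "e_k", actGate = a,
                 actPower = 1, inactGate = b)))
  reg <- rbind(
    .regRow("g_na", "uS", 15, 0, 50),
    .regRow("g_k",  "uS", 3, 0, 15),
    .regRow("g_a",  "uS", 0.5, 0, 5),
    .regRow("m_vhalf", "mV", -35, -50, -10, narrow = c(-40, -30)),
    .regRow("n_vhalf", "mV", -25, -50, -10, narrow = c(-30, -20)),
    .regRow("a_vhalf", "mV", -30, -50, -10, narrow = c(-40, -20)),
    .regRow("b_vhalf", "mV", -10, -40, 10, narrow = c(-20, 0)),
    .regRow("h_vhalf", "mV", -55, -80, -30, narrow = c(-70, -40)),
    .regRow("m_slope", "mV", 7.5, 1, 20, narrow = c(5, 10)),
    .regRow("h_slope", "mV", -7.5, -20, -1, narrow = c(-10, -5)),
    .regRow("n_slope", "mV", 12.5, 1, 25, narrow = c(10, 15)),
    .regRow("a_slope", "mV", 7.5, 1, 20, narrow = c(5, 10)),
    .regRow("b_slope", "mV", -20, -35, -5, narrow = c(-25, -15)),
    .regRow("h_tau", "ms", 20, 1, 100, narrow = c(15, 25)),
    .regRow("n_tau", "ms", 15, 1, 100, narrow = c(10, 20)),
    .regRow("a_tau", "ms", 30, 1, 100, narrow = c(25, 35)),
    .regRow("b_tau", "ms", 47.5, 1, 150, narrow = c(35, 60)),
    .regRow("g_leak", "uS", 0.1, 0, 1, free = FALSE),
    .regRow("e_leak", "mV", -60, -90, -30, free = FALSE),
    .regRow("e_na", "mV", 40, 0, 100, free = FALSE),
    .regRow("e_k",  "mV", -70, -100, -40, free = FALSE),
    .regRow("cm", "nF", 1, 0.5, 2, free = FALSE),
    .regRow("m_tau", "ms", 1, 0.1, 10, free = FALSE),
    .regRow("sigma_sys", "mV/sqrt(ms)", 0.1, 0, 2, free = FALSE),
    .regRow("sigma_obs", "mV", 0.5, 0.05, 10, free = FALSE))
  .newNeuronModel("b4", list(soma), couplingG = 0, somaAreaRatio = 1, reg)
}

#' Build a registered conductance-based model
#'
#' Three model families are available:
#' \describe{
#'   \item{\code{"hh1c"}}{single compartment with leak, transient sodium
#'     (\eqn{m^3 h}) and delayed-rectifier potassium (\eqn{n^4}) currents;
#'     kinetics fitted to the classic squid-axon description.  23 estimable
#'     parameters.}
#'   \item{\code{"motoneuron2c"}}{two-compartment vertebrate motoneuron
#'     (soma + dendrite) after the cat spinal-motoneuron literature:
#'     sodium/potassium and N-type calcium plus calcium-activated potassium
#'     at the soma, N- and L-type calcium plus calcium-activated potassium
#'     at the dendrite, first-order calcium pools in both compartments,
#'     electrical coupling scaled by the soma area ratio.}
#'   \item{\code{"b4"}}{single-compartment snail (Lymnaea) B4-type
#'     motoneuron: leak, transient sodium with instantaneous activation,
#'     delayed-rectifier potassium, and an A-type transient potassium
#'     current; constant relaxation times.  17 estimable parameters.}
#' }
#'
#' @param name one of \code{"hh1c"}, \code{"motoneuron2c"}, \code{"b4"}.
#' @return a \code{\link{NeuronModel}}.
#' @examples
#' m <- buildModel("hh1c")
#' length(freeParams(m))  # 23
#' stateLayout(m)         # "v" "m" "h" "n"
#' @export
buildModel <- function(name) {
  switch(name,
    hh1c = .build_hh1c(),
    motoneuron2c = .build_motoneuron2c(),
    b4 = .build_b4(),
    stop(sprintf("unknown model '%s' (available: hh1c, motoneuron2c, b4)", name)))
}
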