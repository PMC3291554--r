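#' @include models.R
NULL

# Numbers are serialised as %.17g strings so that a write/read round trip
# reproduces doubles bit for bit (YAML's default numeric formatting does not).
.numOut <- function(x) {
  if (is.null(x)) return(NULL)
  vapply(as.numeric(x), function(v) sprintf("%.17g", v), "")
}
.numIn <- function(x) as.numeric(x)

.gateOut <- function(gate) {
  if (is.null(gate)) return(NULL)
  list(name = gate@name, v_half = .numOut(gate@vHalf),
       slope = .numOut(gate@slope), tau_mode = gate@tauMode,
       tau_const = .numOut(gate@tauConst),
       tau_params = as.list(.numOut(gate@tauParams)))
}
.gateIn <- function(g) {
  if (is.null(g)) return(NULL)
  .checkKeys(g, c("name", "v_half", "slope", "tau_mode", "tau_const",
                  "tau_params"), "gate")
  tp <- .numIn(unlist(g$tau_params))
  names(tp) <- c("base", "amplitude", "center", "width")
  new("GateKinetics", name = g$name, vHalf = .numIn(g$v_half),
      slope = .numIn(g$slope), tauMode = g$tau_mode,
      tauConst = .numIn(g$tau_const), tauParams = tp)
}

.checkKeys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    stop(sprintf("unknown key(s) in %s section: %s", where,
                 paste(extra, collapse = ", ")))
  invisible(TRUE)
}

#' Write a model (structure and registry) to a YAML config
#'
#' The file is a complete, lossless description: reading it back yields a
#' model whose drift evaluations are bit-identical.  Unknown keys in a file
#' are rejected on read.
#'
#' @param model a \code{\link{NeuronModel}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeModelConfig <- function(model, path) {
  curOut <- function(cur) {
    list(name = cur@name, e_rev_name = cur@eRevName,
         g_max = .numOut(cur@gMax), e_rev = .numOut(cur@eRev),
         act_gate = .gateOut(cur@actGate), act_power = cur@actPower,
         inact_gate = .gateOut(cur@inactGate), inact_power = cur@inactPower,
         act_mode = cur@actMode,
         kd = if (is.na(cur@caModulation)) NULL else .numOut(cur@caModulation),
         carries_calcium = cur@carriesCalcium)
  }
  compOut <- function(cp) {
    list(name = cp@name, cm = .numOut(cp@cM), g_leak = .numOut(cp@gLeak),
         e_leak = .numOut(cp@eLeak),
         ca = if (cp@hasCalcium)
           list(alpha = .numOut(cp@caParams[["alpha"]]),
                removal = .numOut(cp@caParams[["removal"]])) else NULL,
         currents = lapply(cp@currents, curOut))
  }
  reg <- model@paramRegistry
  regOut <- lapply(seq_len(nrow(reg)), function(i) {
    r <- list(name = reg$name[i], unit = reg$unit[i],
              value = .numOut(reg$value[i]), lower = .numOut(reg$lower[i]),
              upper = .numOut(reg$upper[i]), free = reg$free[i])
    if (!is.na(reg$narrowLower[i])) {
      r$narrow_lower <- .numOut(reg$narrowLower[i])
      r$narrow_upper <- .numOut(reg$narrowUpper[i])
    }
    r
  })
  doc <- list(model = list(name = model@name,
                           coupling_g = .numOut(model@couplingG),
                           soma_area_ratio = .numOut(model@somaAreaRatio),
                           compartments = lapply(model@compartments, compOut),
                           registry = regOut))
  writeLines(yaml::as.yaml(doc), path)
  invisible(path)
}

#' Read a model from a YAML config
#'
#' @param path file written by \code{\link{writeModelConfig}} (or hand
#'   authored to the same schema).
#' @return a \code{\link{NeuronModel}}.
#' @export
readModelConfig <- function(path) {
  doc <- yaml::read_yaml(path)
  .checkKeys(doc, "model", "top-level")
  md <- doc$model
  .checkKeys(md, c("name", "coupling_g", "soma_area_ratio", "compartments",
                   "registry"), "model")
  curIn <- function(cu) {
    .checkKeys(cu, c("name", "e_rev_name", "g_max", "e_rev", "act_gate",
                     "act_power", "inact_gate", "inact_power", "act_mode",
                     "kd", "carries_calcium"), "current")
    new("IonCurrentSpec", name = cu$name, eRevName = cu$e_rev_name,
        gMax = .numIn(cu$g_max), eRev = .numIn(cu$e_rev),
        actGate = .gateIn(cu$act_gate), actPower = as.integer(cu$act_power),
        inactGate = .gateIn(cu$inact_gate),
        inactPower = as.integer(cu$inact_power), actMode = cu$act_mode,
        caModulation = if (is.null(cu$kd)) NA_real_ else .numIn(cu$kd),
        carriesCalcium = isTRUE(cu$carries_calcium))
  }
  compIn <- function(cp) {
    .checkKeys(cp, c("name", "cm", "g_leak", "e_leak", "ca", "currents"),
               "compartment")
    ca <- NULL
    if (!is.null(cp$ca)) {
      .checkKeys(cp$ca, c("alpha", "removal"), "ca")
      ca <- c(alpha = .numIn(cp$ca$alpha), removal = .numIn(cp$ca$removal))
    }
    compartment(cp$name, cM = .numIn(cp$cm), gLeak = .numIn(cp$g_leak),
                eLeak = .numIn(cp$e_leak),
                currents = lapply(cp$currents, curIn), caParams = ca)
  }
  regIn <- do.call(rbind, lapply(md$registry, function(r) {
    .checkKeys(r, c("name", "unit", "value", "lower", "upper", "free",
                    "narrow_lower", "narrow_upper"), "registry")
    nl <- if (is.null(r$narrow_lower)) NA_real_ else .numIn(r$narrow_lower)
    nu <- if (is.null(r$narrow_upper)) NA_real_ else .numIn(r$narrow_upper)
    .regRow(r$name, r$unit, .numIn(r$value), .numIn(r$lower),
            .numIn(r$upper), isTRUE(r$free), c(nl, nu))
  }))
  .newNeuronModel(md$name, lapply(md$compartments, compIn),
                  couplingG = .numIn(md$coupling_g),
                  somaAreaRatio = .numIn(md$soma_area_ratio), regIn)
}
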