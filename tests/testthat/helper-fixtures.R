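# Shared fixtures: tiny protocols and recordings built in code.

stepProtocol <- function(amps, durs) {
  new("CurrentProtocol", steps = data.frame(amplitude = amps, duration = durs),
      totalDuration = sum(durs))
}

# a short hh1c recording with a couple of spikes
hhRecording <- function(totalT = 300, sigmaSys = 0.5, sigmaObs = 1,
                        delta = 0.02, k = 5, seed = 42) {
  m <- buildModel("hh1c")
  p <- generateProtocol(-5, 20, 10, 100, totalT = totalT,
                        seed = deriveSeed(seed, "protocol1"))
  simulateRecording(m, p, noiseSpec(sigmaSys, sigmaObs), delta = delta,
                    k = k, seed = deriveSeed(seed, "recording"))
}

# classic-style reference solution of the hh1c ODEs with deSolve
hhReference <- function(model, protocol, times, v0 = -60, overrides = NULL) {
  testthat::skip_if_not_installed("deSolve")
  x0 <- initialState(model, v0, overrides)
  f <- function(t, x, parms) {
    iinj <- protocolCurrent(protocol, t)
    list(as.numeric(drift(model, x, iinj, overrides)))
  }
  deSolve::ode(as.numeric(x0), times, f, NULL, method = "lsoda",
               rtol = 1e-10, atol = 1e-10)
}
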