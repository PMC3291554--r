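test_that("estimate normalization centres at truth and scales by the window mean", {
  expect_equal(normalizeEstimates(rep(120, 5), thetaTrue = 120), rep(0, 5))
  # constant chain c with truth t maps to (c - t)/|c|
  expect_equal(normalizeEstimates(rep(50, 3), thetaTrue = 40),
               rep((50 - 40) / 50, 3))
  expect_equal(normalizeEstimates(rep(-50, 3), thetaTrue = -40),
               rep((-50 + 40) / 50, 3))
  # unknown-truth mode: constant chain maps to zero
  expect_equal(normalizeEstimates(rep(7, 4)), rep(0, 4))
  # zero window average falls back to the prior width, with a warning
  expect_warning(out <- normalizeEstimates(c(-1, 1), thetaTrue = 0,
                                           priorWidth = 10), "prior")
  expect_equal(out, c(-0.1, 0.1))
  expect_error(normalizeEstimates(numeric()), "empty")
})

test_that("spike detection uses an upward crossing with refractory lockout", {
  tt <- seq(0, 99, by = 0.5)
  v <- rep(-60, length(tt))
  v[tt >= 10 & tt < 11] <- 20
  v[tt >= 11 & tt < 12] <- 10     # still above threshold: no second event
  v[tt >= 40 & tt < 41] <- 15
  sp <- spikeTimes(v, tt)
  expect_length(sp, 2)
  expect_equal(sp, c(10, 40))
})

test_that("the half-width of a symmetric triangular spike is half its base", {
  dt <- 0.01
  tt <- seq(0, 40, by = dt)
  base <- -60; peak <- 40; halfBase <- 2   # rises over 2 ms, falls over 2 ms
  v <- rep(base, length(tt))
  tri <- abs(tt - 20) <= halfBase
  v[tri] <- peak - (peak - base) * abs(tt[tri] - 20) / halfBase
  w <- sossm:::.spikeHalfWidths(v, tt)
  expect_length(w, 1)
  expect_equal(w, halfBase, tolerance = 0.02)
})

test_that("predictive check produces IV points at rest and a nondecreasing IF curve", {
  m <- buildModel("hh1c")
  chk <- b4PredictiveCheck(m, amplitudes = c(0, 2, 15, 20),
                           stepDuration = 400)
  # zero-amplitude step sits at the resting potential
  v0 <- chk$iv$v_steady[chk$iv$amplitude == 0]
  fv <- function(v) unname(drift(m, initialState(m, v), 0)["v"])
  vrest <- uniroot(fv, c(-80, -40))$root
  expect_equal(v0, vrest, tolerance = 0.5)
  # reference-simulation oracle: firing rate nondecreasing in current
  ifr <- chk$ifr[order(chk$ifr$amplitude), ]
  expect_gte(nrow(ifr), 2)
  expect_true(all(diff(ifr$freq_hz) >= 0))
  expect_true(is.finite(chk$halfWidth) && chk$halfWidth > 0)
})

test_that("predictive check warns when nothing spikes", {
  m <- buildModel("hh1c")
  expect_warning(chk <- b4PredictiveCheck(m, amplitudes = c(0, 1),
                                          stepDuration = 100), "no step")
  expect_equal(nrow(chk$ifr), 0)
})

test_that("a tiny noise-only scenario completes, reports and reproduces", {
  sc <- scenario("noise-only", "hh1c",
                 freeParams = c("sigma_sys", "sigma_obs"),
                 protocol = list(ampMin = -5, ampMax = 20, durMin = 10,
                                 durMax = 50, totalT = 150),
                 noise = noiseSpec(0.5, 1),
                 config = smootherConfig(nParticles = 200, lag = 20,
                                         seed = 1),
                 nReplicates = 2, seedBase = 7)
  rep1 <- runScenario(sc)
  expect_true(all(rep1@runs$ok))
  expect_equal(nrow(rep1@parameters), 2 * 2)   # replicates x parameters
  expect_true(all(is.finite(rep1@parameters$estimate)))
  expect_true(all(is.finite(rep1@parameters$norm_discrepancy)))
  # exact reproducibility from (scenario, seed)
  rep2 <- runScenario(sc)
  expect_identical(rep1@parameters, rep2@parameters)
  expect_identical(rep1@runs, rep2@runs)
})

test_that("the noise sweep demands at least two levels and tabulates all parameters", {
  sc <- scenario("sweep", "hh1c", freeParams = c("g_na", "g_k"),
                 protocol = list(ampMin = -5, ampMax = 20, durMin = 10,
                                 durMax = 50, totalT = 100),
                 noise = noiseSpec(0.5, 1),
                 config = smootherConfig(nParticles = 100, lag = 10,
                                         seed = 1),
                 nReplicates = 2, seedBase = 3)
  expect_error(noiseSweep(sc, 1), "two")
  tab <- noiseSweep(sc, c(0.5, 2))
  expect_equal(nrow(tab), 2 * 2)               # levels x free parameters
  expect_true(all(c("sigma_obs", "parameter", "sd_mean", "est_sd")
                  %in% names(tab)))
})

test_that("narrowing kinetic priors does not worsen conductance recovery", {
  m <- buildModel("hh1c")
  free <- c("g_na", "g_k", "m_vhalf", "m_slope", "h_vhalf", "n_vhalf",
            "sigma_sys", "sigma_obs")
  kin <- c("m_vhalf", "m_slope", "h_vhalf", "n_vhalf")
  narrow <- narrowBounds(m)[, kin]
  err <- function(priorBox, repSeed) {
    p <- generateProtocol(-5, 20, 10, 100, totalT = 800,
                          seed = deriveSeed(repSeed, "protocol1"))
    rec <- simulateRecording(m, p, noiseSpec(0.5, 1),
                             seed = deriveSeed(repSeed, "recording"))
    cfg <- smootherConfig(nParticles = 800, lag = 100,
                          seed = deriveSeed(repSeed, "smoother"))
    fit <- runFixedLagSmoother(m, rec, free, cfg, priorBox = priorBox)
    e <- finalEstimate(fit)
    mean(abs(e[c("g_na", "g_k")] - c(120, 36)) / c(120, 36))
  }
  broadErr <- mean(vapply(1:2, function(r) err(NULL, 9100 + r), 0))
  narrowErr <- mean(vapply(1:2, function(r) err(narrow, 9100 + r), 0))
  # "does not worsen", with a pre-declared 0.05 Monte Carlo slack on the
  # mean relative error
  expect_lte(narrowErr, broadErr + 0.05)
})

test_that("multi-trace fitting reduces to the single-trace smoother at G = 1", {
  m <- buildModel("hh1c")
  rec <- hhRecording(totalT = 60, seed = 23)
  cfg <- smootherConfig(nParticles = 120, lag = 10, seed = 2)
  f1 <- runFixedLagSmoother(m, rec, c("g_na", "g_k"), cfg)
  fm <- fitMultiTrace(m, list(rec), c("g_na", "g_k"), cfg)
  expect_identical(f1@thetaMean, fm@thetaMean)
  expect_identical(f1@smoothedStates, fm@smoothedStates)
})

test_that("identical traces yield identical per-trace smoothed states", {
  m <- buildModel("b4")
  pr <- stepProtocol(c(0, 2.5, 0), c(20, 60, 20))
  rec <- simulateRecording(m, pr, noiseSpec(0, 0.5), seed = 3,
                           thetaTrue = NULL)
  cfg <- smootherConfig(nParticles = 150, lag = 10, seed = 4)
  # sigma_sys fixed at zero so propagation is deterministic given theta
  fit <- fitMultiTrace(m, list(rec, rec, rec, rec), c("g_na", "g_k"), cfg,
                       fixed = c(sigma_sys = 0))
  sm <- fit@smoothedStates
  lay <- stateLayout(m)
  ref <- unname(sm[, paste0("trace1.", lay)])
  for (g in 2:4)
    expect_identical(unname(sm[, paste0("trace", g, ".", lay)]), ref)
  expect_error(fitMultiTrace(m, list(), "g_na", cfg), "at least one")
})

test_that("mismatched sample grids are rejected for joint fits", {
  m <- buildModel("hh1c")
  r1 <- hhRecording(totalT = 60, seed = 1)
  r2 <- hhRecording(totalT = 80, seed = 2)
  cfg <- smootherConfig(nParticles = 50, lag = 5, seed = 1)
  expect_error(fitMultiTrace(m, list(r1, r2), "g_na", cfg), "sample grid")
})
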