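test_that("a noise-free EM step equals one explicit Euler step", {
  m <- buildModel("hh1c")
  x <- initialState(m, -55)
  delta <- 0.02
  manual <- as.numeric(x) + as.numeric(drift(m, x, 3)) * delta
  stepped <- emStep(m, x, 3, noiseSpec(0, 0), delta)
  expect_equal(as.numeric(stepped), manual)
})

test_that("EM voltage increments have variance sigma^2 * delta", {
  m <- buildModel("hh1c")
  # silence the drift so only the diffusion term moves the voltage
  ov <- c(g_na = 0, g_k = 0, g_leak = 0)
  x <- initialState(m, -60, overrides = ov)
  delta <- 0.01
  n <- 20000
  set.seed(3)
  dv <- replicate(n, emStep(m, x, 0, noiseSpec(sigmaSys = 1), delta,
                            overrides = ov)[["v"]] - x[["v"]])
  # sampling oracle: Var(dV) = delta, MC standard error of a variance
  se <- delta * sqrt(2 / (n - 1))
  expect_lt(abs(var(dv) - delta), 3 * se)
  expect_lt(abs(mean(dv)), 3 * sqrt(delta / n))
})

test_that("gates stay in [0,1] under positive noise at the boundary", {
  m <- buildModel("hh1c")
  x <- initialState(m, -60)
  x["m"] <- 1
  set.seed(1)
  for (i in 1:50) {
    xn <- emStep(m, x, 0, noiseSpec(0, 0, gateNoiseSd = c(m = 5)), 0.01)
    expect_true(all(xn[c("m", "h", "n")] >= 0 & xn[c("m", "h", "n")] <= 1))
  }
})

test_that("protocol generation respects ranges, counts and determinism", {
  p <- generateProtocol(-2, 8, 10, 200, totalT = 1000, seed = 9)
  expect_gte(nrow(p@steps), 5)                       # 1000/200 at least
  expect_true(all(p@steps$amplitude >= -2 & p@steps$amplitude <= 8))
  expect_equal(sum(p@steps$duration), 1000)
  p2 <- generateProtocol(-2, 8, 10, 200, totalT = 1000, seed = 9)
  expect_identical(p@steps, p2@steps)
  expect_error(generateProtocol(5, 5, 1, 2, 10), "ampMin")
  expect_error(generateProtocol(0, 1, 0, 2, 10), "durMin")
})

test_that("protocol amplitudes are uniform (KS test over many steps)", {
  p <- generateProtocol(0, 1, 1, 2, totalT = 15000, seed = 12)
  amps <- p@steps$amplitude[-nrow(p@steps)]
  expect_gt(length(amps), 9000)
  expect_gt(stats::ks.test(amps, "punif")$p.value, 0.01)
})

test_that("noise-free recordings decimate the simulated voltage exactly", {
  m <- buildModel("hh1c")
  p <- stepProtocol(c(0, 5, 0), c(20, 30, 50))
  rec <- simulateRecording(m, p, noiseSpec(0, 0), delta = 0.02, k = 5,
                           seed = 4)
  expect_equal(nrow(rec@y), floor(100 / 0.1))
  expect_identical(unname(rec@y[, 1]), unname(rec@hidden[, "v"]))
})

test_that("a sustained suprathreshold step elicits spikes matching an ODE reference", {
  m <- buildModel("hh1c")
  p <- stepProtocol(c(0, 15, 0), c(50, 300, 150))
  rec <- simulateRecording(m, p, noiseSpec(0, 0), delta = 0.01, k = 10,
                           seed = 4)
  v <- rec@hidden[, "v"]
  tt <- sampleTimes(rec)
  spikes <- spikeTimes(v, tt)
  expect_gte(length(spikes), 1)
  ref <- hhReference(m, p, tt)
  refSpikes <- spikeTimes(ref[, 2], tt)
  expect_equal(length(spikes), length(refSpikes))
  expect_lt(max(abs(spikes - refSpikes)), 0.5)
})

test_that("EM converges to the reference solution as delta shrinks", {
  m <- buildModel("hh1c")
  # strong but subthreshold steps: pointwise voltage comparison is
  # meaningful here, away from the steep spike flanks
  p <- stepProtocol(c(0, 2.5, -3, 1.5, 0), c(100, 100, 100, 100, 100))
  tt <- seq(0, 500 - 0.2, by = 0.2)
  ref <- hhReference(m, p, tt)
  errs <- vapply(c(0.04, 0.02, 0.01), function(delta) {
    k <- round(0.2 / delta)
    rec <- simulateRecording(m, p, noiseSpec(0, 0), delta = delta, k = k,
                             seed = 1)
    max(abs(rec@hidden[, "v"] - ref[, 2]))
  }, 0)
  expect_true(all(diff(errs) < 0))   # monotone improvement as delta halves
  expect_lt(errs[3], 1)              # < 1 mV at delta = 0.01 ms
})

test_that("the B4-type model fires repetitively above ~2 nA", {
  b4 <- buildModel("b4")
  pr <- stepProtocol(c(0, 2.5, 0), c(100, 600, 100))
  rec <- simulateRecording(b4, pr, noiseSpec(0, 0), seed = 1)
  sp <- spikeTimes(rec@hidden[, "v"], sampleTimes(rec))
  expect_gte(length(sp), 3)
  # subthreshold below ~1 nA
  prSub <- stepProtocol(c(0, 0.8, 0), c(100, 600, 100))
  recSub <- simulateRecording(b4, prSub, noiseSpec(0, 0), seed = 1)
  expect_length(spikeTimes(recSub@hidden[, "v"], sampleTimes(recSub)), 0)
})

test_that("instability is reported rather than silently propagated", {
  m <- buildModel("hh1c")
  p <- stepProtocol(c(2000), c(20))   # absurd drive at a coarse step
  expect_error(
    simulateRecording(m, p, noiseSpec(0, 0), delta = 1, k = 1, seed = 1),
    "instability|500")
})

test_that("identical seeds give bit-identical recordings", {
  r1 <- hhRecording(totalT = 100, seed = 77)
  r2 <- hhRecording(totalT = 100, seed = 77)
  expect_identical(r1@y, r2@y)
  expect_identical(r1@hidden, r2@hidden)
})

test_that("recording files round trip losslessly", {
  rec <- hhRecording(totalT = 100, seed = 5)
  path <- tempfile(fileext = ".csv")
  writeRecording(rec, path)
  back <- readRecording(path)
  expect_identical(dim(back@y), dim(rec@y))
  expect_equal(unname(back@y), unname(rec@y))
  expect_equal(unname(back@iInj), unname(rec@iInj))
  expect_equal(unname(back@hidden), unname(rec@hidden))
  expect_identical(back@sampleInterval, rec@sampleInterval)
  expect_identical(back@channelMap, rec@channelMap)
  expect_equal(back@meta$sigma_obs, rec@meta$sigma_obs)
})

test_that("malformed recording files fail with a line number", {
  rec <- hhRecording(totalT = 50, seed = 5)
  path <- tempfile(fileext = ".csv")
  writeRecording(rec, path)
  lines <- readLines(path)
  # ragged row
  bad <- lines
  bad[20] <- paste0(bad[20], ",99")
  writeLines(bad, path)
  expect_error(readRecording(path), "line 20")
  # missing sampling-interval header
  writeLines(lines[-1], path)
  expect_error(readRecording(path), "sample_interval")
})
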