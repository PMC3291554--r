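test_that("the Gaussian observation density behaves as a density", {
  # at the mean with unit SD: -0.5 log(2 pi) per channel
  expect_equal(logObservationDensity(-60, -60, 1), -0.5 * log(2 * pi))
  # independence across channels: two-channel value is the sum
  expect_equal(logObservationDensity(c(-60, -55), c(-61, -54), 2),
               logObservationDensity(-60, -61, 2) +
                 logObservationDensity(-55, -54, 2))
  # quadrature oracle: integrates to one over y
  f <- function(y) exp(vapply(y, function(yy)
    logObservationDensity(yy, -60, 2.5), 0))
  expect_equal(stats::integrate(f, -60 - 50, -60 + 50)$value, 1,
               tolerance = 1e-6)
  expect_error(logObservationDensity(0, 0, 0), "positive")
})

test_that("reweighting is normalized, proportional and shift invariant", {
  w <- rep(0.25, 4)
  expect_equal(reweight(w, rep(-3, 4)), w)            # identical likelihoods
  w2 <- reweight(c(0.5, 0.5), log(c(3, 1)))
  expect_equal(w2, c(0.75, 0.25))                     # likelihood ratio 3:1
  ll <- c(-1, -5, -2)
  expect_equal(reweight(rep(1 / 3, 3), ll), reweight(rep(1 / 3, 3), ll + 50))
  expect_error(reweight(rep(1 / 3, 3), rep(-Inf, 3)), "degenerate")
  expect_error(reweight(c(0.9, 0.9), c(0, 0)), "normalized")
})

test_that("effective sample size spans [1, N] with the right landmarks", {
  expect_equal(effectiveSampleSize(rep(1 / 100, 100)), 100)
  expect_equal(effectiveSampleSize(c(1, rep(0, 9))), 1)
  expect_equal(effectiveSampleSize(c(0.5, 0.5, rep(0, 8))), 2)
  expect_error(effectiveSampleSize(c(0.2, 0.2)), "normalized")
})

test_that("systematic resampling has its structural properties", {
  # uniform weights: every particle copied exactly once
  idx <- systematicResample(rep(1 / 8, 8), u = 0.37)
  expect_identical(sort(idx), 1:8)
  # one-hot weights: all copies of the lone survivor
  idx <- systematicResample(c(0, 0, 0, 1, 0), u = 0.5)
  expect_true(all(idx == 4))
  # unbiasedness: E[resampled mean] equals the weighted mean
  set.seed(8)
  w <- stats::runif(20); w <- w / sum(w)
  x <- stats::rnorm(20)
  target <- sum(w * x)
  reps <- replicate(10000, mean(x[systematicResample(w)]))
  se <- stats::sd(reps) / sqrt(length(reps))
  expect_lt(abs(mean(reps) - target), 3 * se)
})

test_that("ensemble buffering, smoothing and fixed-lag resampling cohere", {
  set.seed(2)
  ens <- particleEnsemble(theta = matrix(stats::rnorm(20), 10, 2),
                          tau = rep(0.1, 10), lag = 3L)
  expect_error(smoothedExpectation(ens, function(r) 1), "not ready")
  for (i in 1:5) ens <- pushBuffer(ens)      # buffer capped at lag + 1
  expect_length(ens@buffer, 4L)
  expect_equal(smoothedExpectation(ens, function(r) 1, 2), 1)
  # lag offset 0 reproduces the filter mean of theta component 1
  expect_equal(smoothedExpectation(ens, function(r) r[1], 0),
               sum(ens@weights * ens@theta[, 1]))
  # linearity
  f0 <- smoothedExpectation(ens, function(r) r[2], 1)
  expect_equal(smoothedExpectation(ens, function(r) 3 * r[2] + 1, 1),
               3 * f0 + 1)
  # resampling preserves buffer depth and resets the weights
  ens@weights <- normalizeLogWeights(stats::rnorm(10))
  res <- resampleFixedLag(ens, u = 0.2)
  expect_length(res@buffer, 4L)
  expect_equal(res@weights, rep(0.1, 10))
  # the whole trajectory of a selected particle is copied
  idx <- systematicResample(ens@weights, u = 0.2)
  expect_equal(res@buffer[[2]], ens@buffer[[2]][idx, , drop = FALSE])
})

test_that("ensemble propagation moves states, not weights", {
  m <- buildModel("hh1c")
  x0 <- initialState(m, -60)
  n <- 30
  ens <- particleEnsemble(theta = matrix(rep(c(120, 36), each = n), n, 2,
                                         dimnames = list(NULL, c("g_na", "g_k"))),
                          tau = rep(0.1, n),
                          states = matrix(rep(x0, each = n), n, 4,
                                          dimnames = list(NULL, names(x0))))
  w0 <- normalizeLogWeights(stats::rnorm(n))
  ens@weights <- w0
  # noise-free: identical particles stay identical, weights untouched
  set.seed(2)
  out <- propagateEnsemble(ens, m, iInj = 5, noiseSpec(0, 0))
  expect_identical(out@weights, w0)
  expect_equal(max(apply(out@states, 2, function(cc) diff(range(cc)))), 0)
  expect_false(isTRUE(all.equal(out@states[1, ], ens@states[1, ])))
  # CLT bound after a single substep: the ensemble-mean voltage stays
  # within 3 sigma_sys sqrt(delta)/sqrt(n) of the deterministic prediction
  set.seed(3)
  sSys <- 1
  det1 <- propagateEnsemble(ens, m, iInj = 5, noiseSpec(0, 0), k = 1L)
  noisy <- propagateEnsemble(ens, m, iInj = 5, noiseSpec(sSys, 0), k = 1L)
  expect_lt(abs(mean(noisy@states[, "v"]) - det1@states[1, "v"]),
            3 * sSys * sqrt(0.02) / sqrt(n))
  expect_error(propagateEnsemble(particleEnsemble(matrix(1, 1, 1)), m, 0),
               "empty")
})

test_that("the bootstrap filter matches the Kalman filter on a linear-Gaussian model", {
  # x_t = phi x_{t-1} + w, w ~ N(0, q^2);  y_t = x_t + v, v ~ N(0, r^2)
  phi <- 0.9; q <- 0.6; r <- 0.8
  set.seed(21)
  T <- 120
  x <- numeric(T); x[1] <- stats::rnorm(1, 0, q / sqrt(1 - phi^2))
  for (t in 2:T) x[t] <- phi * x[t - 1] + stats::rnorm(1, 0, q)
  y <- x + stats::rnorm(T, 0, r)
  # closed-form Kalman oracle
  kal <- function(y) {
    mPrev <- 0; pPrev <- q^2 / (1 - phi^2); out <- numeric(length(y))
    for (t in seq_along(y)) {
      mp <- phi * mPrev; pp <- phi^2 * pPrev + q^2
      if (t == 1) { mp <- 0; pp <- q^2 / (1 - phi^2) }
      kg <- pp / (pp + r^2)
      mPrev <- mp + kg * (y[t] - mp); pPrev <- (1 - kg) * pp
      out[t] <- mPrev
    }
    out
  }
  kf <- kal(y)
  pf <- bootstrapFilter(y,
    init = function(n) stats::rnorm(n, 0, q / sqrt(1 - phi^2)),
    propagate = function(xp) phi * xp + stats::rnorm(length(xp), 0, q),
    loglik = function(xp, yt) stats::dnorm(yt, xp, r, log = TRUE),
    n = 5000)
  statSd <- q / sqrt(1 - phi^2)
  expect_lt(mean(abs(pf$mean - kf)), 0.05 * statSd)
  expect_true(all(pf$ess >= 1 & pf$ess <= 5000))
})

test_that("particle-filter error shrinks roughly like 1/sqrt(N)", {
  phi <- 0.9; q <- 0.6; r <- 0.8
  set.seed(33)
  T <- 150
  x <- numeric(T); x[1] <- stats::rnorm(1, 0, q / sqrt(1 - phi^2))
  for (t in 2:T) x[t] <- phi * x[t - 1] + stats::rnorm(t > 0, 0, q)
  y <- x + stats::rnorm(T, 0, r)
  kal <- function(y) {
    mPrev <- 0; pPrev <- q^2 / (1 - phi^2); out <- numeric(length(y))
    for (t in seq_along(y)) {
      mp <- if (t == 1) 0 else phi * mPrev
      pp <- if (t == 1) q^2 / (1 - phi^2) else phi^2 * pPrev + q^2
      kg <- pp / (pp + r^2)
      mPrev <- mp + kg * (y[t] - mp); pPrev <- (1 - kg) * pp
      out[t] <- mPrev
    }
    out
  }
  kf <- kal(y)
  run <- function(n) {
    errs <- vapply(1:3, function(i) {
      pf <- bootstrapFilter(y,
        init = function(nn) stats::rnorm(nn, 0, q / sqrt(1 - phi^2)),
        propagate = function(xp) phi * xp + stats::rnorm(length(xp), 0, q),
        loglik = function(xp, yt) stats::dnorm(yt, xp, r, log = TRUE),
        n = n)
      mean(abs(pf$mean - kf))
    }, 0)
    mean(errs)
  }
  ratio <- run(1000) / run(10000)
  expect_gt(ratio, sqrt(10) / 2)
  expect_lt(ratio, sqrt(10) * 2)
})

test_that("the full smoother replays bit-identically under a fixed seed", {
  m <- buildModel("hh1c")
  rec <- hhRecording(totalT = 60, seed = 19)
  cfg <- smootherConfig(nParticles = 150, lag = 10, seed = 5)
  f1 <- runFixedLagSmoother(m, rec, c("g_na", "g_k"), cfg)
  f2 <- runFixedLagSmoother(m, rec, c("g_na", "g_k"), cfg)
  expect_identical(f1@thetaMean, f2@thetaMean)
  expect_identical(f1@smoothedStates, f2@smoothedStates)
  expect_identical(f1@ess, f2@ess)
})

test_that("smoother run-level invariants hold on a two-compartment fit", {
  m <- buildModel("motoneuron2c")
  set.seed(31)
  protos <- lapply(1:2, function(i)
    generateProtocol(-0.5, 2.5, 20, 100, totalT = 150, seed = 30 + i))
  rec <- simulateRecording(m, protos, noiseSpec(0.3, 1),
                           observedCompartments = 1:2, seed = 33)
  free <- c("g_na", "g_k", "g_can_s")
  cfg <- smootherConfig(nParticles = 300, lag = 20, seed = 6)
  fit <- runFixedLagSmoother(m, rec, free, cfg)
  N <- cfg@nParticles
  expect_true(all(fit@ess >= 1 - 1e-9 & fit@ess <= N + 1e-9))
  b <- fit@priorBox
  for (p in free) {
    expect_true(all(fit@thetaMean[, p] >= b["lower", p] - 1e-9))
    expect_true(all(fit@thetaMean[, p] <= b["upper", p] + 1e-9))
  }
  sm <- fit@smoothedStates
  gateCols <- setdiff(colnames(sm), c("v_s", "v_d", "ca_s", "ca_d"))
  expect_true(all(sm[, gateCols] >= 0 & sm[, gateCols] <= 1))
  expect_true(all(sm[, c("ca_s", "ca_d")] >= 0))
  expect_true(all(is.finite(fit@thetaMean)))
})

test_that("the smoother validates its inputs", {
  m <- buildModel("hh1c")
  rec <- hhRecording(totalT = 30, seed = 1)
  cfg <- smootherConfig(nParticles = 50, lag = 5, seed = 1)
  expect_error(runFixedLagSmoother(m, rec, "g_unknown", cfg), "registry")
  expect_error(runFixedLagSmoother(m, rec, "cm", cfg), "fixed")
  badCfg <- smootherConfig(nParticles = 50, lag = 5, delta = 0.05, seed = 1)
  expect_error(runFixedLagSmoother(m, rec, "g_na", badCfg),
               "sample interval")
})

test_that("fixed-lag smoothing beats filtering at high observation noise", {
  m <- buildModel("hh1c")
  rec <- hhRecording(totalT = 250, sigmaObs = 5, seed = 55)
  runL <- function(L) {
    cfg <- smootherConfig(nParticles = 400, lag = L, seed = 9)
    fit <- runFixedLagSmoother(m, rec, character(0), cfg)
    sqrt(mean((fit@smoothedStates[, "v"] - rec@hidden[, "v"])^2))
  }
  rmseSmooth <- runL(100)
  rmseFilter <- runL(0)
  expect_lt(rmseSmooth, rmseFilter)
  expect_lt(rmseSmooth, 2 * 5)      # well inside twice the observation noise
})
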