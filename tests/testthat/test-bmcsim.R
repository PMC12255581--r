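test_that("generator encodes equilibrium, exchange conservation, dimensions", {
  env <- waterOnlyEnv(t1 = 1.3, t2 = 0.4)
  gen <- assembleGenerator(env, 0, 0, 0)
  # thermal equilibrium is the unique fixed point with RF off
  M <- solve(gen@A, -gen@C)
  expect_equal(M, c(0, 0, 1), tolerance = 1e-12)

  # exchange-only dynamics conserve total longitudinal magnetization
  envx <- CESTEnvironment(water = Pool(1, 1e6, 1e6),
                          cestPools = list(p = Pool(2e-3, 1e6, 1e6,
                                                    k = 200, dw = 0)))
  genx <- assembleGenerator(envx, 0, 0, 0)
  M0 <- c(0, 0, 0.4, 0, 0, 0.2 * 2e-3)
  M1 <- propagate(M0, genx, 0.05)
  expect_equal(M1[3] + M1[6], M0[3] + M0[6], tolerance = 1e-6)

  # water + 3 CEST + MT -> 13 state entries
  env3 <- CESTEnvironment(
    water = Pool(1, 1.3, 0.07),
    cestPools = list(a = Pool(1e-3, 1, 0.1, 50, 3.5),
                     b = Pool(1e-3, 1, 0.1, 1000, 2),
                     c = Pool(4e-3, 1.3, 0.005, 16, -3.5)),
    mtPool = MTPool(0.05, 1, 1e-5, 30, 0))
  gen3 <- assembleGenerator(env3, 1, 0, 0)
  expect_identical(dim(gen3@A), c(13L, 13L))
  # physical parameters give a dissipative generator
  expect_true(all(Re(eigen(gen3@A, only.values = TRUE)$values) <= 1e-10))
})

test_that("propagate solves the affine ODE exactly", {
  env <- waterOnlyEnv(t1 = 0.8, t2 = 0.1)
  gen <- assembleGenerator(env, 0, 0, 0)
  M0 <- c(0, 0, 0)
  expect_identical(propagate(M0, gen, 0), M0)
  # closed-form T1 recovery from saturation
  for (t in c(0.1, 0.5, 2)) {
    M <- propagate(M0, gen, t)
    expect_equal(M[3], 1 - exp(-t / 0.8), tolerance = 1e-9)
  }
  # semigroup property under RF
  genRF <- assembleGenerator(env, 2, 0.3, 500)
  Ma <- propagate(propagate(c(0, 0, 1), genRF, 0.01), genRF, 0.01)
  Mb <- propagate(c(0, 0, 1), genRF, 0.02)
  expect_equal(Ma, Mb, tolerance = 1e-9)
})

test_that("crusher zeroes transverse components and is idempotent", {
  env <- CESTEnvironment(water = Pool(1, 1, 0.1),
                         cestPools = list(p = Pool(1e-3, 1, 0.1, 100, 2)),
                         mtPool = MTPool(0.05, 1, 1e-5, 30, 0))
  M <- c(0.3, 0.4, 0.5, 0.01, -0.02, 1e-3, 0.04)
  Mc <- applyCrusher(M, env)
  expect_equal(Mc, c(0, 0, 0.5, 0, 0, 1e-3, 0.04))
  expect_identical(applyCrusher(Mc, env), Mc)
})

test_that("zero-amplitude saturation yields Z identically 1", {
  env <- randomEnvFixed <- waterOnlyEnv()
  sq <- CESTSequence(c(-2, 0, 2), PulseTrain(makeRectPulse(10e-3, 0), 3L, 2e-3),
                     tRec = 1)
  z <- simulateZspectrum(sq, env)
  expect_equal(values(z), rep(1, 3), tolerance = 1e-12)
})

test_that("long CW saturation matches the single-pool steady-state formula", {
  t1 <- 1; t2 <- 0.2
  env <- waterOnlyEnv(t1, t2)
  b1 <- 2
  sq <- CESTSequence(seq(-5, 5, by = 1),
                     PulseTrain(makeRectPulse(15, b1, raster = 1e-3), 1L, 0),
                     tRec = 10)
  z <- simulateZspectrum(sq, env, maxDt = 1e-3)
  w1 <- 2 * pi * 42.5764 * b1
  dw <- offsets(z) * 2 * pi * 42.5764 * 3
  r1 <- 1 / t1; r2 <- 1 / t2
  zExpect <- r1 * (r2^2 + dw^2) / (r1 * (r2^2 + dw^2) + w1^2 * r2)
  expect_lt(max(abs(values(z) - zExpect)), 1e-3)
})

test_that("matrix-exponential propagation matches Runge-Kutta integration", {
  set.seed(7)
  sq <- shortRectSequence(offsets = c(-2.2, 0.4, 3.1))
  for (i in 1:6) {
    env <- randomEnv(nMax = 2)
    zExp <- simulateZspectrum(sq, env, maxDt = 1e-3)
    zRK <- rk4Zspectrum(sq, env, maxDt = 1e-3, h = 2e-5)
    expect_lt(max(abs(values(zExp) - values(zRK))), 1e-5)
  }
})

test_that("Z-spectra are physical and offset-order invariant", {
  set.seed(11)
  sq <- shortRectSequence()
  for (i in 1:5) {
    env <- randomEnv(nMax = 2)
    z <- simulateZspectrum(sq, env)
    expect_true(all(values(z) >= -1 & values(z) <= 1 + 1e-9))
  }
  env <- larginineEnvironment(30)
  sqShuffled <- CESTSequence(c(3, -1, 0, -3, 1), sq@train, tRec = sq@tRec)
  sqSorted <- CESTSequence(c(-3, -1, 0, 1, 3), sq@train, tRec = sq@tRec)
  z1 <- simulateZspectrum(sqShuffled, env)
  z2 <- simulateZspectrum(sqSorted, env)
  expect_equal(values(z1), values(z2), tolerance = 1e-12)
})

test_that("halving the propagation step leaves shaped-pulse Z unchanged", {
  # discretization error is second order in the step; at 20 us the Z change
  # from a further halving is below 1e-6
  env <- larginineEnvironment(20)
  sh <- makeSincGaussPulse(50e-3, 2, raster = 5e-6)
  sq <- CESTSequence(c(0.7), PulseTrain(sh, 1L, 0), tRec = 2)
  zCoarse <- simulateZspectrum(sq, env, maxDt = 1e-5)
  zFine <- simulateZspectrum(sq, env, maxDt = 5e-6)
  expect_lt(max(abs(values(zCoarse) - values(zFine))), 1e-6)
})

test_that("direct water saturation dominates: Z minimum at 0 ppm", {
  env <- larginineEnvironment(20)
  sq <- buildAPTw3T(offsets = seq(-4, 4, by = 1))
  sq@train@shape <- makeSincGaussPulse(50e-3, 2, raster = 1e-4)
  z <- simulateZspectrum(sq, env)
  expect_equal(offsets(z)[which.min(values(z))], 0)
})

test_that("gapped pulse trains produce sidebands absent under equal-RMS CW", {
  env <- larginineEnvironment(20)
  # offsets straddling sideband maxima/minima of the 55 ms pulse period
  off <- sort(c(seq(1.5, 2.1, by = 0.012), -seq(1.5, 2.1, by = 0.012)))
  trainPulsed <- PulseTrain(makeRectPulse(50e-3, 2), 36L, 5e-3)
  tsat <- 36 * 50e-3 + 35 * 5e-3
  trainCW <- PulseTrain(makeRectPulse(tsat, 2 * sqrt(36 * 50e-3 / tsat),
                                      raster = 1e-3), 1L, 0)
  zP <- simulateZspectrum(CESTSequence(off, trainPulsed, tRec = 3.5), env,
                          maxDt = 1e-3)
  zC <- simulateZspectrum(CESTSequence(off, trainCW, tRec = 3.5), env,
                          maxDt = 1e-3)
  swing <- function(z) diff(range(values(z)[offsets(z) > 0]))
  # the pulsed train's sideband dips dominate the CW residual fringes
  expect_gt(swing(zP), 5 * swing(zC))
  # and they alternate in sign (oscillatory structure, not a monotone slope)
  d <- diff(values(zP)[offsets(zP) > 0])
  expect_gt(sum(diff(sign(d)) != 0), 5)
})
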