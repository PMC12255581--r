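wasabiModelSpectrum <- function(x, b1, db0, c0, d0, tp = 5e-3,
                                f0 = 42.5764 * 3) {
  w1 <- 2 * pi * 42.5764 * b1
  dwr <- 2 * pi * f0 * (x - db0)
  we2 <- w1^2 + dwr^2
  ZSpectrum(x, abs(c0 - d0 * (w1^2 / we2) * sin(sqrt(we2) * tp / 2)^2))
}

test_that("normalization divides by the reference and validates it", {
  off <- c(-2, 0, 1, 3)
  z <- normalizeSpectrum(rep(0.5, 4), off, 0.5)
  expect_equal(values(z), rep(1, 4))
  z2 <- normalizeSpectrum(c(0.5, 0.4, 0.5, 0.5), off, 0.5)
  expect_equal(values(z2)[2], 0.8)
  expect_error(normalizeSpectrum(1:4, off, 0), "s0")
  expect_error(normalizeSpectrum(1:4, off, -1), "s0")
})

test_that("linear interpolation is exact at nodes and averages midpoints", {
  z <- ZSpectrum(c(-2, -1, 0, 1, 2), c(1, 0.8, 0.2, 0.7, 0.95))
  same <- interpolateSpectrum(z, offsets(z), method = "linear")
  expect_identical(values(same), values(z))
  mid <- interpolateSpectrum(z, 0.5, method = "linear")
  expect_equal(values(mid), (0.2 + 0.7) / 2)
  expect_error(interpolateSpectrum(z, 2.5, method = "linear"), "extrapolation")
})

test_that("smoothing spline recovers a noisy parabola within 2 sigma", {
  set.seed(42)
  x <- seq(-2, 2, by = 0.1)
  truth <- 0.3 + 0.1 * x^2
  z <- ZSpectrum(x, truth + rnorm(length(x), sd = 0.01))
  fit <- interpolateSpectrum(z, x, method = "smoothing_spline")
  expect_lt(max(abs(values(fit) - truth)), 0.02)
  # smoothing leaves a nonzero node residual while linear is exact at nodes
  expect_gt(max(abs(values(fit) - values(z))), 0)
  lin <- interpolateSpectrum(z, x, method = "linear")
  expect_equal(values(lin), values(z), tolerance = 1e-12)
})

test_that("MTR asymmetry has the Z(-dw) - Z(+dw) convention", {
  x <- seq(-4, 4, by = 0.5)
  even <- ZSpectrum(x, 1 - 0.5 * exp(-x^2))
  a <- mtrAsym(even)
  expect_equal(values(a), rep(0, length(values(a))), tolerance = 1e-12)
  z <- ZSpectrum(c(-3, 0, 3), c(0.9, 0.1, 0.8))
  expect_equal(values(mtrAsym(z))[offsets(mtrAsym(z)) == 3], 0.1,
               tolerance = 1e-12)
  expect_error(mtrAsym(ZSpectrum(c(0.5, 1, 2), c(1, 1, 1))), "both sides")
  # antisymmetry under spectrum mirroring
  set.seed(3)
  v <- 1 - 0.5 * exp(-x^2) + 0.05 * sin(x) + rnorm(length(x), sd = 0.01)
  zf <- ZSpectrum(x, v)
  zm <- ZSpectrum(-x, v)
  expect_equal(values(mtrAsym(zm)), -values(mtrAsym(zf)), tolerance = 1e-12)
})

test_that("simulated APTw L-arginine asymmetry peaks near +3 ppm", {
  z <- simulateZspectrum(buildAPTw3T(), larginineEnvironment(20))
  a <- mtrAsym(z)
  pk <- offsets(a)[which.max(values(a))]
  # exchange broadening at 2 uT shifts the apparent peak slightly below the
  # 3 ppm guanidinium resonance
  expect_gte(pk, 2.25)
  expect_lte(pk, 3.25)
  expect_gt(max(values(a)), 0.02)
})

test_that("B0 correction shifts spectra and is near-invertible", {
  x <- seq(-3, 3, by = 0.1)
  shifted <- ZSpectrum(x, 1 - 0.8 * exp(-((x - 0.2)^2) / 0.05))
  expect_identical(values(b0Correct(shifted, 0)), values(shifted))
  corr <- b0Correct(shifted, 0.2)
  expect_equal(offsets(corr)[which.min(values(corr))], 0, tolerance = 1e-9)
  # range preservation under linear interpolation
  expect_gte(min(values(corr)), min(values(shifted)) - 1e-12)
  expect_lte(max(values(corr)), max(values(shifted)) + 1e-12)
  # near-inverse on a smooth spectrum
  smooth <- ZSpectrum(x, 1 - 0.3 * exp(-x^2 / 2))
  back <- b0Correct(b0Correct(smooth, 0.15), -0.15)
  ref <- values(smooth)[match(offsets(back), x)]
  expect_lt(max(abs(values(back) - ref)), 2e-3)
  expect_error(b0Correct(smooth, 5), "range")
})

test_that("wasabi fit recovers parameters from noiseless model spectra", {
  x <- seq(-2, 2, by = 0.1)
  f <- wasabiFit(wasabiModelSpectrum(x, 3.7, 0.1, 0.9, 1.4))
  expect_lt(abs(f@b1Abs - 3.7) / 3.7, 0.01)
  expect_lt(abs(f@db0 - 0.1), 0.01)
  f0fit <- wasabiFit(wasabiModelSpectrum(x, 4.2, 0, 1, 2))
  expect_lt(abs(f0fit@db0), 0.01)
  set.seed(1)
  errs <- vapply(1:50, function(i) {
    b1 <- runif(1, 2.5, 5)
    d0 <- runif(1, -0.3, 0.3)
    ft <- wasabiFit(wasabiModelSpectrum(x, b1, d0, runif(1, 0.8, 1.1),
                                        runif(1, 1, 2)))
    c(abs(ft@b1Abs - b1) / b1, abs(ft@db0 - d0))
  }, numeric(2))
  expect_lt(stats::median(errs[1, ]), 0.01)
  expect_lt(stats::median(errs[2, ]), 0.01)
})

test_that("wasabi fit recovers simulator ground truth end to end", {
  env <- larginineEnvironment(20)
  env@db0 <- 0.08
  env@relB1 <- 1.05
  z <- simulateZspectrum(buildWASABI(), env)
  f <- wasabiFit(z)
  expect_lt(abs(f@b1Abs - 3.7 * 1.05) / (3.7 * 1.05), 0.02)
  expect_lt(abs(f@db0 - 0.08), 0.02)
})

test_that("ROI reduction returns per-offset mean and spread", {
  off <- c(-1, 0, 1)
  data <- array(NA_real_, c(2, 2, 3))
  data[1, 1, ] <- c(0.4, 0.2, 0.4)
  data[2, 1, ] <- c(0.6, 0.2, 0.4)
  s0 <- matrix(c(1, 1, 0, 0), 2, 2)
  stk <- new("ImageStack", data = data, offsets = off, s0 = s0,
             provenance = list())
  one <- roiReduce(stk, matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2))
  expect_equal(values(one$mean), c(0.4, 0.2, 0.4))
  expect_equal(one$sd, c(0, 0, 0))
  both <- roiReduce(stk, matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2))
  expect_equal(values(both$mean)[1], 0.5)
  expect_equal(both$sd[1], stats::sd(c(0.4, 0.6)))
  expect_error(roiReduce(stk, matrix(FALSE, 2, 2)), "empty mask")
})
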