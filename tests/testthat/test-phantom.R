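# a small fast phantom/sequence pair used across these tests
smallPhantom <- function(tubeRadius = 2, ...)
  makeDigitalPhantom(grid = 24L, tubeRadius = tubeRadius, ...)

coarseAPTw <- function(offsets = seq(-4, 4, by = 1)) {
  sq <- buildAPTw3T(offsets)
  sq@train@shape <- makeSincGaussPulse(50e-3, 2, raster = 1e-3)
  sq
}

test_that("digital phantom has five disjoint labelled tubes", {
  ph <- makeDigitalPhantom()
  labs <- sort(unique(as.vector(ph@labels)))
  expect_identical(labs, 0:5)
  # tubes are discs of near-equal rasterized area
  counts <- table(ph@labels[ph@labels != 0])
  expect_true(all(counts > 0.8 * pi * 7^2))
  expect_lt(diff(range(counts)), 0.2 * pi * 7^2)
  expect_identical(names(ph@environments), as.character(1:5))
  # tube 2 carries 27 mM L-arginine
  expect_equal(ph@environments[["2"]]@cestPools[[1]]@f, 3 * 27 / 111000,
               tolerance = 1e-12)
  # homogeneous fields by default
  expect_true(all(ph@db0Map == 0))
  expect_true(all(ph@relB1Map == 1))
  expect_error(makeDigitalPhantom(grid = 16, tubeRadius = 6), "overlap")
})

test_that("field inhomogeneity produces smooth nonzero maps", {
  ph <- smallPhantom(fieldInhomogeneity = list(db0 = 0.2, relB1 = 0.1))
  expect_gt(max(abs(ph@db0Map)), 0.1)
  expect_lt(max(abs(ph@db0Map)), 0.2 + 1e-9)
  expect_true(all(ph@relB1Map > 0.85 & ph@relB1Map < 1.15))
})

test_that("noiseless stacks are deterministic and tube-uniform", {
  ph <- smallPhantom()
  sq <- coarseAPTw()
  stk <- simulateStack(sq, ph, noiseSd = 0, seed = 1)
  stk2 <- simulateStack(sq, ph, noiseSd = 0, seed = 99)
  expect_identical(stk@data, stk2@data)
  # all tube-1 voxels share one spectrum
  d <- dim(stk@data)
  flat <- matrix(stk@data, d[1] * d[2], d[3])
  vox <- flat[as.vector(ph@labels == 1L), ]
  expect_true(all(apply(vox, 2, function(col) all(col == col[1]))))
  # background is masked
  expect_true(all(is.na(flat[as.vector(ph@labels == 0L), ])))
  expect_true(all(stk@s0[ph@labels == 0L] == 0))
})

test_that("noisy stacks are seed-reproducible and mean-consistent", {
  ph <- smallPhantom(tubeRadius = 4)
  sq <- coarseAPTw(offsets = c(-3, 0, 3))
  a <- simulateStack(sq, ph, noiseSd = 0.01, seed = 7)
  b <- simulateStack(sq, ph, noiseSd = 0.01, seed = 7)
  expect_identical(a@data, b@data)
  c2 <- simulateStack(sq, ph, noiseSd = 0.01, seed = 8)
  expect_false(identical(a@data, c2@data))
  # ROI mean over >= 40 voxels within 5 standard errors of noiseless truth
  clean <- simulateStack(sq, ph, noiseSd = 0, seed = 1)
  mask <- ph@labels == 1L
  nVox <- sum(mask)
  expect_gte(nVox, 40)
  mu <- roiReduce(a, mask)$mean
  mu0 <- roiReduce(clean, mask)$mean
  expect_lt(max(abs(values(mu) - values(mu0))), 5 * 0.01 / sqrt(nVox))
})

test_that("stack round trip through NIfTI + sidecars is lossless", {
  ph <- smallPhantom()
  sq <- coarseAPTw(offsets = c(-2, -1, 0, 1, 2))
  stk <- simulateStack(sq, ph, noiseSd = 0.005, seed = 3)
  dir <- withr::local_tempdir()
  p <- file.path(dir, "stack")
  writeStack(stk, p)
  back <- readStack(p)
  expect_equal(back@data, stk@data, tolerance = 0)
  expect_equal(back@s0, stk@s0, tolerance = 0)
  expect_identical(back@offsets, stk@offsets)
  expect_identical(back@provenance$seed, stk@provenance$seed)
  # evaluation of the reread stack is identical
  m1 <- parametricMap(stk, "mtrasym", ppm = 2)
  m2 <- parametricMap(back, "mtrasym", ppm = 2)
  expect_identical(m1, m2)
  # missing sidecar is an error
  file.remove(file.path(p, "offsets.txt"))
  expect_error(readStack(p), "offsets.txt")
})

test_that("MT tubes depress the far-off-resonance baseline", {
  ph <- smallPhantom()
  sq <- coarseAPTw(offsets = c(-4, -3.5, -0.5, 0.5, 3.5, 4))
  stk <- simulateStack(sq, ph, noiseSd = 0, seed = 1)
  far <- vapply(1:5, function(i) {
    r <- roiReduce(stk, ph@labels == i)$mean
    mean(values(r)[abs(offsets(r)) >= 3.5])
  }, numeric(1))
  expect_lt(max(far[3:5]), min(far[1:2]) - 0.02)
})

test_that("parametric maps recover field truth and concentration contrast", {
  ph <- smallPhantom()
  stkW <- simulateStack(buildWASABI(seq(-2, 2, by = 0.2)), ph,
                        noiseSd = 0, seed = 1)
  b0m <- parametricMap(stkW, "b0")
  b1m <- parametricMap(stkW, "b1")
  inside <- ph@labels != 0
  # homogeneous phantom: recovered B0 shift is zero, B1 is nominal
  expect_lt(max(abs(b0m[inside])), 0.02)
  expect_lt(max(abs(b1m[inside] - 3.7) / 3.7), 0.02)
  # background voxels carry no fit
  expect_true(all(is.na(b0m[!inside])))

  stkA <- simulateStack(coarseAPTw(seq(-4, 4, by = 0.5)), ph,
                        noiseSd = 0, seed = 1)
  m <- parametricMap(stkA, "mtrasym", ppm = 3.0)
  expect_gt(mean(m[ph@labels == 5]), mean(m[ph@labels == 1]))
  expect_true(all(is.na(m[!inside])))
})
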