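# shared fixtures: tiny environments and a fast coarse sequence

waterOnlyEnv <- function(t1 = 1, t2 = 0.2) {
  CESTEnvironment(water = Pool(1, t1, t2))
}

# small random environment with up to nMax CEST pools (water + pools)
randomEnv <- function(nMax = 2) {
  nPools <- sample.int(nMax + 1, 1) - 1L
  pools <- lapply(seq_len(nPools), function(i)
    Pool(f = runif(1, 1e-4, 5e-3), t1 = runif(1, 0.5, 3),
         t2 = runif(1, 0.01, 1), k = runif(1, 20, 1000),
         dw = runif(1, -4, 4)))
  if (nPools) names(pools) <- paste0("p", seq_len(nPools))
  CESTEnvironment(water = Pool(1, runif(1, 0.5, 3), runif(1, 0.05, 1)),
                  cestPools = pools)
}

# coarse sequence that keeps simulation tests fast
shortRectSequence <- function(offsets = c(-3, -1, 0, 1, 3), b1 = 3,
                              tp = 10e-3, n = 2L, td = 5e-3, tRec = 2) {
  CESTSequence(offsets, PulseTrain(makeRectPulse(tp, b1), n, td),
               tRec = tRec)
}

# RK4 integration of dM/dt = A M + C over piecewise-constant segments;
# independent of the matrix-exponential path
rk4Propagate <- function(M, A, C, duration, h = 2e-5) {
  nStep <- max(1L, ceiling(duration / h))
  h <- duration / nStep
  for (s in seq_len(nStep)) {
    k1 <- drop(A %*% M) + C
    k2 <- drop(A %*% (M + h / 2 * k1)) + C
    k3 <- drop(A %*% (M + h / 2 * k2)) + C
    k4 <- drop(A %*% (M + h * k3)) + C
    M <- M + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  M
}

# full Z-spectrum via RK4 through the discretized train: the brute-force
# oracle mirroring simulateZspectrum's sequencing
rk4Zspectrum <- function(seq, env, maxDt = 1e-3, h = 2e-5) {
  scl <- 2 * pi * env@gammaOver2pi * env@b0
  train <- seq@train
  pools <- c(list(env@water), unname(env@cestPools))
  n <- 3L * length(pools) + as.integer(!is.null(env@mtPool))
  init <- numeric(n)
  for (i in seq_along(pools))
    init[3 * (i - 1) + 3] <- pools[[i]]@f * (1 - exp(-seq@tRec / pools[[i]]@t1))
  if (!is.null(env@mtPool))
    init[n] <- env@mtPool@f * (1 - exp(-seq@tRec / env@mtPool@t1))
  one <- function(off, rfOn) {
    segs <- discretize(train@shape, off, maxDt)
    gen0 <- assembleGenerator(env, 0, 0, off)
    M <- init
    for (p in seq_len(train@nPulses)) {
      for (j in seq_len(nrow(segs))) {
        g <- if (rfOn)
          assembleGenerator(env, segs$amplitude[j],
                            segs$phase[j] + train@phases[p], off)
        else gen0
        M <- rk4Propagate(M, g@A, g@C, segs$dt[j], h)
      }
      if (p < train@nPulses)
        M <- rk4Propagate(M, gen0@A, gen0@C, train@interPulseDelay, h)
    }
    M[3]
  }
  zsat <- vapply(seq@offsets * scl, one, numeric(1), rfOn = TRUE)
  s0 <- one(0, rfOn = FALSE)
  ZSpectrum(seq@offsets, zsat / s0)
}
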