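## Bloch-McConnell integration by piecewise-constant matrix-exponential
## propagation. State layout: (Mx, My, Mz) for water, then for each CEST
## pool in order, then a single Mz entry for the MT pool if present. All
## magnetizations are in units of the equilibrium water Mz (= 1).

.stateDim <- function(env) {
  3L * (1L + length(env@cestPools)) + as.integer(!is.null(env@mtPool))
}

.ppmScale <- function(env) 2 * pi * env@gammaOver2pi * env@b0  # rad/s per ppm

#' Assemble the Bloch-McConnell generator for one constant RF segment
#'
#' Builds the affine ODE dM/dt = A M + C in the frame rotating at the RF
#' frequency: transverse relaxation, residual precession of each pool at
#' `(dw + db0) * w0 - offset`, RF nutation at `w1 = 2 pi gamma (B1 relB1)`,
#' exchange terms obeying detailed balance (`k_water->pool = k * f`), T1
#' recovery towards `Mz = f`, and for the MT pool a saturation rate
#' `Rrfmt = pi * w1^2 * g(offset)` with a Lorentzian absorption lineshape
#' `g(x) = (T2m / pi) / (1 + (x T2m)^2)`.
#'
#' @param env a [CESTEnvironment-class].
#' @param amplitude nominal RF amplitude (uT); scaled by `env@relB1`.
#' @param phase RF phase (rad).
#' @param offset RF frequency offset from water (rad/s).
#' @return a [GeneratorPair-class].
#' @export
assembleGenerator <- function(env, amplitude, phase = 0, offset = 0) {
  stopifnot(is(env, "CESTEnvironment"))
  if (amplitude < 0) stop("amplitude must be >= 0")
  pools <- c(list(env@water), unname(env@cestPools))
  np <- length(pools)
  hasMT <- !is.null(env@mtPool)
  n <- 3L * np + as.integer(hasMT)
  A <- matrix(0, n, n)
  C <- numeric(n)
  scl <- .ppmScale(env)
  w1 <- 2 * pi * env@gammaOver2pi * amplitude * env@relB1
  wx <- w1 * cos(phase)
  wy <- w1 * sin(phase)
  for (i in seq_len(np)) {
    p <- pools[[i]]
    d <- (p@dw + env@db0) * scl - offset  # residual precession, rad/s
    xi <- 3L * (i - 1L) + 1L; yi <- xi + 1L; zi <- xi + 2L
    A[xi, xi] <- A[xi, xi] - 1 / p@t2
    A[yi, yi] <- A[yi, yi] - 1 / p@t2
    A[zi, zi] <- A[zi, zi] - 1 / p@t1
    A[xi, yi] <- A[xi, yi] + d
    A[yi, xi] <- A[yi, xi] - d
    A[yi, zi] <- A[yi, zi] + wx
    A[zi, yi] <- A[zi, yi] - wx
    A[xi, zi] <- A[xi, zi] - wy
    A[zi, xi] <- A[zi, xi] + wy
    C[zi] <- p@f / p@t1
  }
  # exchange between water (pool 1) and each CEST pool
  if (np > 1L) for (i in 2:np) {
    k <- pools[[i]]@k
    fi <- pools[[i]]@f
    for (c in 0:2) {
      wc <- 1L + c
      pc <- 3L * (i - 1L) + 1L + c
      A[wc, wc] <- A[wc, wc] - k * fi
      A[wc, pc] <- A[wc, pc] + k
      A[pc, wc] <- A[pc, wc] + k * fi
      A[pc, pc] <- A[pc, pc] - k
    }
  }
  if (hasMT) {
    m <- env@mtPool
    zm <- n
    zw <- 3L
    dm <- (m@dw + env@db0) * scl - offset
    g <- if (m@lineshape == "lorentzian")
      (m@t2 / pi) / (1 + (dm * m@t2)^2) else 0
    A[zm, zm] <- -1 / m@t1 - pi * w1^2 * g - m@k
    A[zm, zw] <- A[zm, zw] + m@k * m@f
    A[zw, zm] <- A[zw, zm] + m@k
    A[zw, zw] <- A[zw, zw] - m@k * m@f
    C[zm] <- m@f / m@t1
  }
  GeneratorPair(A, C)
}

## exp of the one-dimensional affine augmentation [[A, C], [0, 0]] * dt
.augExp <- function(A, C, dt) {
  n <- length(C)
  aug <- rbind(cbind(A, C), 0) * dt
  as.matrix(Matrix::expm(Matrix::Matrix(aug)))
}

#' Propagate a state vector through one constant segment
#'
#' Exact solution of dM/dt = A M + C over `dt` via the matrix exponential
#' of the one-dimensional affine augmentation (scaling-and-squaring Pade).
#'
#' @param M state vector (see [assembleGenerator()] for the layout).
#' @param gen a [GeneratorPair-class].
#' @param dt duration (s), >= 0.
#' @return the propagated state vector.
#' @export
propagate <- function(M, gen, dt) {
  stopifnot(is(gen, "GeneratorPair"))
  if (dt < 0) stop("dt must be >= 0")
  if (dt == 0) return(M)
  n <- length(gen@C)
  if (length(M) != n) stop("state dimension mismatch")
  drop(.augExp(gen@A, gen@C, dt) %*% c(M, 1))[seq_len(n)]
}

#' Zero all transverse magnetization (ideal crusher gradient)
#'
#' @param M state vector.
#' @param env the [CESTEnvironment-class] defining the state layout.
#' @return `M` with every Mx and My entry set to 0.
#' @export
applyCrusher <- function(M, env) {
  np <- 1L + length(env@cestPools)
  idx <- as.vector(outer(c(1L, 2L), 3L * (seq_len(np) - 1L), `+`))
  M[idx] <- 0
  M
}

## recovery from zero state: Mz_i = f_i (1 - exp(-tRec / T1_i)); the
## readout is not modelled, so every offset starts from this state.
.recoveredState <- function(env, tRec) {
  pools <- c(list(env@water), unname(env@cestPools))
  M <- numeric(.stateDim(env))
  for (i in seq_along(pools))
    M[3L * (i - 1L) + 3L] <- pools[[i]]@f * (1 - exp(-tRec / pools[[i]]@t1))
  if (!is.null(env@mtPool))
    M[length(M)] <- env@mtPool@f * (1 - exp(-tRec / env@mtPool@t1))
  M
}

#' Simulate a Z-spectrum
#'
#' For every offset of the sequence: recovery of `tRec` from the
#' post-crusher (zero-transverse) state, propagation through the
#' discretized pulse train with free evolution during the inter-pulse
#' gaps, an ideal crusher, and readout of water Mz. The reference S0 comes
#' from the sequence's M0 policy (an RF-off scan of identical timing, or a
#' saturated far-offset scan). Offsets are simulated independently; their
#' order does not matter.
#'
#' @param seq a [CESTSequence-class].
#' @param env a [CESTEnvironment-class].
#' @param maxDt maximal propagation step during shaped pulses (s).
#' @return a [ZSpectrum-class] over the sequence offsets.
#' @examples
#' \donttest{
#' z <- simulateZspectrum(buildAPTw3T(), larginineEnvironment(20))
#' }
#' @export
simulateZspectrum <- function(seq, env, maxDt = 1e-4) {
  stopifnot(is(seq, "CESTSequence"), is(env, "CESTEnvironment"))
  train <- seq@train
  shape <- train@shape
  n <- .stateDim(env)
  Minit <- c(.recoveredState(env, seq@tRec), 1)
  tsum <- timingSummary(train)
  expCache <- new.env(parent = emptyenv())
  segExp <- function(amp, phase, offsetRad, dt) {
    key <- sprintf("%.15g|%.15g|%.15g|%.15g", amp, phase, offsetRad, dt)
    got <- expCache[[key]]
    if (!is.null(got)) return(got)
    gen <- assembleGenerator(env, amp, phase, offsetRad)
    E <- .augExp(gen@A, gen@C, dt)
    expCache[[key]] <- E
    E
  }
  segs0 <- discretize(shape, 0, maxDt)
  # exp(A dt1) exp(A dt2) = exp(A (dt1 + dt2)): merge runs of identical
  # amplitude and phase into one exponential (exact, and turns a long
  # rectangular pulse into a single segment)
  run <- cumsum(c(TRUE, diff(segs0$amplitude) != 0 | diff(segs0$phase) != 0))
  segs <- data.frame(amplitude = segs0$amplitude[!duplicated(run)],
                     phase = segs0$phase[!duplicated(run)],
                     dt = as.numeric(tapply(segs0$dt, run, sum)))
  satMz <- function(offsetRad) {
    pulseProp <- function(pulsePhase) {
      P <- diag(n + 1L)
      for (j in seq_len(nrow(segs)))
        P <- segExp(segs$amplitude[j], segs$phase[j] + pulsePhase,
                    offsetRad, segs$dt[j]) %*% P
      P
    }
    uph <- unique(train@phases)
    Pp <- lapply(uph, pulseProp)
    Pd <- if (train@nPulses > 1L && train@interPulseDelay > 0)
      segExp(0, 0, offsetRad, train@interPulseDelay) else NULL
    v <- Minit
    for (p in seq_len(train@nPulses)) {
      v <- Pp[[match(train@phases[p], uph)]] %*% v
      if (!is.null(Pd) && p < train@nPulses) v <- Pd %*% v
    }
    M <- applyCrusher(drop(v)[seq_len(n)], env)
    M[3L]
  }
  freeMz <- function() {
    # RF-off scan: same timing, generator identical during pulses and gaps
    gen0 <- assembleGenerator(env, 0, 0, 0)
    M <- propagate(Minit[seq_len(n)], gen0, tsum@tSat)
    applyCrusher(M, env)[3L]
  }
  scl <- .ppmScale(env)
  zsat <- vapply(seq@offsets, function(off) {
    z <- satMz(off * scl)
    if (!is.finite(z))
      stop(sprintf("propagation failed at offset %g ppm", off))
    z
  }, numeric(1))
  s0 <- if (seq@m0Policy == "separate") freeMz()
        else satMz(seq@m0Offset * scl)
  if (!is.finite(s0) || s0 <= 0)
    stop("non-positive reference signal S0")
  ZSpectrum(seq@offsets, zsat / s0)
}
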