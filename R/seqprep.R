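## Pulse construction and discretization for CEST pre-saturation blocks.

#' Rectangular RF pulse
#'
#' Constant-amplitude block pulse, as used by WASABI.
#'
#' @param duration pulse duration t_p (s), > 0.
#' @param amplitude amplitude (uT), >= 0; for a rect pulse peak and RMS
#'   amplitude coincide.
#' @param phase constant phase (rad).
#' @param raster sample raster (s).
#' @return an [RFShape-class].
#' @examples
#' p <- makeRectPulse(5e-3, 3.7)
#' duration(p)
#' @export
makeRectPulse <- function(duration, amplitude, phase = 0, raster = 1e-5) {
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (raster > duration) stop("raster must not exceed duration")
  n <- max(1L, round(duration / raster))
  RFShape(rep(amplitude, n), rep(phase, n), duration / n)
}

#' Gaussian-apodized sinc RF pulse
#'
#' Sinc envelope with `sideLobes` lobes on each side of the main lobe,
#' apodized by a Gaussian of standard deviation `duration / 4`, and rescaled
#' so that the root-mean-square amplitude over the pulse equals `b1Rms`.
#' Negative envelope lobes are stored as positive amplitude with phase pi.
#'
#' The RMS convention matches continuous-wave power-equivalent reporting of
#' shaped saturation pulses in APTw protocols.
#'
#' @param duration pulse duration t_p (s), > 0.
#' @param b1Rms RMS amplitude (uT), > 0.
#' @param sideLobes sinc side lobes per side.
#' @param raster sample raster (s).
#' @return an [RFShape-class].
#' @examples
#' p <- makeSincGaussPulse(50e-3, 2)
#' sqrt(mean(p@amplitude^2))  # 2 uT
#' @export
makeSincGaussPulse <- function(duration, b1Rms, sideLobes = 2L,
                               raster = 1e-5) {
  if (!is.finite(duration) || duration <= 0)
    stop("duration must be > 0")
  if (!is.finite(b1Rms) || b1Rms <= 0)
    stop("b1Rms must be > 0")
  if (raster > duration)
    stop("raster must not exceed duration")
  n <- max(2L, round(duration / raster))
  dt <- duration / n
  # sample centres, symmetric about the pulse midpoint
  t <- (seq_len(n) - 0.5) * dt - duration / 2
  x <- 2 * (sideLobes + 1) * t / duration      # sinc argument, zeros at integers
  env <- ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  sigma <- duration / 4
  env <- env * exp(-t^2 / (2 * sigma^2))
  env <- env / sqrt(mean(env^2)) * b1Rms
  RFShape(abs(env), ifelse(env < 0, pi, 0), dt)
}

#' Saturation timing summary
#'
#' @param train a [PulseTrain-class].
#' @return a [TimingSummary-class] with
#'   `tSat = n * t_p + (n - 1) * t_d` and duty cycle `t_p / (t_p + t_d)`
#'   (1 for a single pulse).
#' @examples
#' tr <- PulseTrain(makeSincGaussPulse(50e-3, 2), 36, 5e-3)
#' timingSummary(tr)  # t_sat 1.975 s, DC 91%
#' @export
timingSummary <- function(train) {
  stopifnot(is(train, "PulseTrain"))
  tp <- duration(train@shape)
  n <- train@nPulses
  td <- train@interPulseDelay
  new("TimingSummary",
      tSat = n * tp + (n - 1) * td,
      dutyCycle = if (n > 1L) tp / (tp + td) else 1.0)
}

#' APTw 3T sinc-Gauss saturation sequence
#'
#' Pulse train of 36 sinc-Gauss pulses (t_p = 50 ms, t_d = 5 ms,
#' B1rms = 2 uT, DC = 91%, t_sat = 1.975 s) with 3.5 s recovery, the
#' standard amide-proton-transfer-weighted protocol at 3 T.
#'
#' @param offsets saturation offsets (ppm); default -4 to +4 in 0.25 steps.
#' @return a [CESTSequence-class].
#' @export
buildAPTw3T <- function(offsets = seq(-4, 4, by = 0.25)) {
  shape <- makeSincGaussPulse(50e-3, 2)
  train <- PulseTrain(shape, 36L, 5e-3)
  CESTSequence(offsets, train, tRec = 3.5, m0Policy = "separate",
               name = "APTw_3T")
}

#' WASABI B0/B1 mapping sequence
#'
#' A single 5 ms rectangular pulse at 3.7 uT; the short strong pulse drives
#' off-resonant Rabi oscillations whose pattern encodes B0 (water peak
#' position) and B1 (oscillation frequency/amplitude).
#'
#' @param offsets saturation offsets (ppm); default -2 to +2 in 0.1 steps.
#' @param tRec recovery delay (s); default 12 s for near-complete recovery.
#' @return a [CESTSequence-class].
#' @export
buildWASABI <- function(offsets = seq(-2, 2, by = 0.1), tRec = 12) {
  shape <- makeRectPulse(5e-3, 3.7)
  train <- PulseTrain(shape, 1L, 0)
  CESTSequence(offsets, train, tRec = tRec, m0Policy = "separate",
               name = "WASABI")
}

#' Discretize an RF shape into piecewise-constant segments
#'
#' Groups raster samples into segments no longer than `maxDt`, with segment
#' boundaries on sample edges. Each segment carries the root-mean-square
#' amplitude of its samples (preserving RF power), the power-weighted
#' circular mean phase, the frequency offset, and its duration. Segment
#' durations sum exactly to the pulse duration.
#'
#' @param shape an [RFShape-class].
#' @param offset RF frequency offset (rad/s) attached to every segment.
#' @param maxDt maximal segment duration (s), > 0.
#' @return data.frame with columns `amplitude` (uT), `phase` (rad),
#'   `offset` (rad/s), `dt` (s).
#' @export
discretize <- function(shape, offset = 0, maxDt = 1e-4) {
  stopifnot(is(shape, "RFShape"))
  if (!is.finite(maxDt) || maxDt <= 0) stop("maxDt must be > 0")
  n <- length(shape@amplitude)
  if (n == 0L) stop("empty shape")
  per <- max(1L, floor(maxDt / shape@raster))
  grp <- (seq_len(n) - 1L) %/% per
  # break groups at phase discontinuities (e.g. sinc lobe sign flips) so
  # every segment has one well-defined phase
  phaseRun <- cumsum(c(TRUE, diff(shape@phase) != 0))
  grp <- cumsum(c(TRUE, diff(grp) != 0 | diff(phaseRun) != 0))
  amp2 <- shape@amplitude^2
  # power-weighted complex mean encodes the dominant phase of each group
  zre <- vapply(split(amp2 * cos(shape@phase), grp), sum, numeric(1))
  zim <- vapply(split(amp2 * sin(shape@phase), grp), sum, numeric(1))
  cnt <- vapply(split(amp2, grp), length, numeric(1))
  pw <- vapply(split(amp2, grp), sum, numeric(1))
  ph <- ifelse(pw > 0, atan2(zim, zre), 0)
  data.frame(amplitude = sqrt(pw / cnt),
             phase = ph,
             offset = offset,
             dt = cnt * shape@raster,
             row.names = NULL)
}
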