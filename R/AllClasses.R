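#' @import methods
NULL

## ---------------------------------------------------------------------------
## RF waveforms and pulse trains
## ---------------------------------------------------------------------------

#' Sampled RF waveform
#'
#' An RF pulse sampled on a uniform raster. Amplitudes are stored in microtesla
#' and are non-negative; sign inversions of the envelope (e.g. sinc side lobes)
#' are represented by a phase of pi radians.
#'
#' @slot amplitude numeric vector, sample amplitudes (uT), all >= 0.
#' @slot phase numeric vector, per-sample phase (rad), same length.
#' @slot raster numeric(1), seconds per sample.
#' @export
setClass("RFShape", representation(
  amplitude = "numeric",
  phase = "numeric",
  raster = "numeric"
))

setValidity("RFShape", function(object) {
  msg <- character()
  if (length(object@amplitude) < 1L)
    msg <- c(msg, "shape must contain at least one sample")
  if (length(object@phase) != length(object@amplitude))
    msg <- c(msg, "amplitude and phase must have equal length")
  if (any(!is.finite(object@amplitude)) || any(object@amplitude < 0))
    msg <- c(msg, "amplitudes must be finite and >= 0")
  if (any(!is.finite(object@phase)))
    msg <- c(msg, "phases must be finite")
  if (length(object@raster) != 1L || !is.finite(object@raster) ||
      object@raster <= 0)
    msg <- c(msg, "raster must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @describeIn RFShape-class Constructor.
#' @param amplitude,phase,raster see slots.
#' @export
RFShape <- function(amplitude, phase = rep(0, length(amplitude)),
                    raster = 1e-5) {
  new("RFShape", amplitude = as.numeric(amplitude),
      phase = as.numeric(phase), raster = as.numeric(raster))
}

#' Saturation pulse train
#'
#' A train of `nPulses` repetitions of one [RFShape-class], separated by an
#' inter-pulse delay `t_d` during which the RF is off, with an optional phase
#' offset per pulse (phase cycling).
#'
#' @slot shape the [RFShape-class] repeated in the train.
#' @slot nPulses integer(1), number of pulses (>= 1).
#' @slot interPulseDelay numeric(1), delay t_d between pulses (s, >= 0).
#' @slot phases numeric, per-pulse phase offsets (rad), length `nPulses`.
#' @export
setClass("PulseTrain", representation(
  shape = "RFShape",
  nPulses = "integer",
  interPulseDelay = "numeric",
  phases = "numeric"
))

setValidity("PulseTrain", function(object) {
  msg <- character()
  if (length(object@nPulses) != 1L || object@nPulses < 1L)
    msg <- c(msg, "nPulses must be a single integer >= 1")
  if (length(object@phases) != object@nPulses)
    msg <- c(msg, "length(phases) must equal nPulses")
  if (length(object@interPulseDelay) != 1L || object@interPulseDelay < 0)
    msg <- c(msg, "interPulseDelay must be a single number >= 0")
  if (length(msg)) msg else TRUE
})

#' @describeIn PulseTrain-class Constructor.
#' @param shape,nPulses,interPulseDelay,phases see slots.
#' @export
PulseTrain <- function(shape, nPulses = 1L, interPulseDelay = 0,
                       phases = rep(0, nPulses)) {
  new("PulseTrain", shape = shape, nPulses = as.integer(nPulses),
      interPulseDelay = as.numeric(interPulseDelay),
      phases = as.numeric(phases))
}

#' Saturation timing summary
#'
#' Total saturation time and duty cycle of a pulse train:
#' `tSat = n * t_p + (n - 1) * t_d`, `dutyCycle = t_p / (t_p + t_d)` for
#' n > 1 and exactly 1 for a single pulse.
#'
#' @slot tSat numeric(1), total saturation duration (s).
#' @slot dutyCycle numeric(1), RF duty cycle in (0, 1].
#' @export
setClass("TimingSummary", representation(
  tSat = "numeric",
  dutyCycle = "numeric"
))

#' CEST pre-saturation sequence
#'
#' A frequency-offset list, the saturation pulse train applied at every
#' offset, the recovery delay before each saturation block, and the policy
#' used to obtain the unsaturated reference signal S0.
#'
#' @slot offsets numeric, saturation frequency offsets (ppm), no duplicates.
#' @slot train the [PulseTrain-class].
#' @slot tRec numeric(1), recovery delay before each offset (s).
#' @slot m0Policy character(1), `"separate"` for a dedicated RF-off scan or
#'   `"far-offset"` to use a saturated scan at `m0Offset`.
#' @slot m0Offset numeric(1), far offset in ppm (`NA` unless
#'   `m0Policy == "far-offset"`).
#' @slot name character(1), label.
#' @export
setClass("CESTSequence", representation(
  offsets = "numeric",
  train = "PulseTrain",
  tRec = "numeric",
  m0Policy = "character",
  m0Offset = "numeric",
  name = "character"
))

setValidity("CESTSequence", function(object) {
  msg <- character()
  if (length(object@offsets) < 1L || any(!is.finite(object@offsets)))
    msg <- c(msg, "offsets must be finite and non-empty")
  if (anyDuplicated(object@offsets))
    msg <- c(msg, "offsets must not contain duplicates")
  if (length(object@tRec) != 1L || !is.finite(object@tRec) || object@tRec < 0)
    msg <- c(msg, "tRec must be a single number >= 0")
  if (!object@m0Policy %in% c("separate", "far-offset"))
    msg <- c(msg, "m0Policy must be 'separate' or 'far-offset'")
  if (object@m0Policy == "far-offset" && !is.finite(object@m0Offset))
    msg <- c(msg, "m0Offset must be finite when m0Policy is 'far-offset'")
  if (length(msg)) msg else TRUE
})

#' @describeIn CESTSequence-class Constructor.
#' @param offsets,train,tRec,m0Policy,m0Offset,name see slots.
#' @export
CESTSequence <- function(offsets, train, tRec = 0, m0Policy = "separate",
                         m0Offset = NA_real_, name = "cest") {
  new("CESTSequence", offsets = as.numeric(offsets), train = train,
      tRec = as.numeric(tRec), m0Policy = m0Policy,
      m0Offset = as.numeric(m0Offset), name = name)
}

#' Piecewise-constant RF segment
#'
#' Segments produced by [discretize()]: one constant amplitude, phase and
#' frequency offset held for `dt` seconds. Returned as a data.frame with
#' columns `amplitude`, `phase`, `offset`, `dt`; no S4 class is needed for
#' this plain table.
#' @name RFSegment
NULL

## ---------------------------------------------------------------------------
## Exchange environments
## ---------------------------------------------------------------------------

#' Proton pool
#'
#' One exchanging proton pool in a Bloch-McConnell environment.
#'
#' @slot f numeric(1), relative proton fraction (water = 1).
#' @slot t1 numeric(1), longitudinal relaxation time (s).
#' @slot t2 numeric(1), transverse relaxation time (s).
#' @slot k numeric(1), exchange rate towards water (Hz).
#' @slot dw numeric(1), chemical shift relative to water (ppm).
#' @export
setClass("Pool", representation(
  f = "numeric", t1 = "numeric", t2 = "numeric",
  k = "numeric", dw = "numeric"
))

setValidity("Pool", function(object) {
  msg <- character()
  one <- function(x) length(x) == 1L && is.finite(x)
  if (!one(object@f) || object@f < 0) msg <- c(msg, "f must be >= 0")
  if (!one(object@t1) || object@t1 <= 0) msg <- c(msg, "t1 must be > 0")
  if (!one(object@t2) || object@t2 <= 0) msg <- c(msg, "t2 must be > 0")
  if (!one(object@k) || object@k < 0) msg <- c(msg, "k must be >= 0")
  if (!one(object@dw)) msg <- c(msg, "dw must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn Pool-class Constructor.
#' @param f,t1,t2,k,dw see slots.
#' @export
Pool <- function(f, t1, t2, k = 0, dw = 0) {
  new("Pool", f = as.numeric(f), t1 = as.numeric(t1), t2 = as.numeric(t2),
      k = as.numeric(k), dw = as.numeric(dw))
}

#' Semisolid magnetization transfer pool
#'
#' A macromolecular pool tracked by its longitudinal component only; RF
#' saturation enters through an absorption lineshape.
#'
#' @slot lineshape character(1), `"lorentzian"` or `"none"`.
#' @export
setClass("MTPool", contains = "Pool",
         representation(lineshape = "character"))

setValidity("MTPool", function(object) {
  if (!object@lineshape %in% c("lorentzian", "none"))
    "lineshape must be 'lorentzian' or 'none'" else TRUE
})

#' @describeIn MTPool-class Constructor.
#' @param f,t1,t2,k,dw,lineshape see slots.
#' @export
MTPool <- function(f, t1, t2, k = 0, dw = 0, lineshape = "lorentzian") {
  new("MTPool", f = as.numeric(f), t1 = as.numeric(t1), t2 = as.numeric(t2),
      k = as.numeric(k), dw = as.numeric(dw), lineshape = lineshape)
}

setClassUnion("MTPoolOrNull", c("MTPool", "NULL"))

#' Bloch-McConnell exchange environment
#'
#' Water pool, CEST pools, an optional semisolid MT pool, the static field
#' and per-voxel field inhomogeneity scalars.
#'
#' @slot water [Pool-class] for water (f = 1, dw = 0, k = 0).
#' @slot cestPools named list of [Pool-class] objects.
#' @slot mtPool an [MTPool-class] or `NULL`.
#' @slot b0 numeric(1), static field (T).
#' @slot gammaOver2pi numeric(1), gyromagnetic ratio / 2 pi (MHz/T).
#' @slot db0 numeric(1), static field shift (ppm).
#' @slot relB1 numeric(1), relative B1 scale (dimensionless, > 0).
#' @slot extra list, unknown yaml keys preserved on round trip.
#' @export
setClass("CESTEnvironment", representation(
  water = "Pool",
  cestPools = "list",
  mtPool = "MTPoolOrNull",
  b0 = "numeric",
  gammaOver2pi = "numeric",
  db0 = "numeric",
  relB1 = "numeric",
  extra = "list"
))

setValidity("CESTEnvironment", function(object) {
  msg <- character()
  if (object@water@f != 1) msg <- c(msg, "water pool must have f = 1")
  if (object@water@dw != 0 || object@water@k != 0)
    msg <- c(msg, "water pool must have dw = 0 and k = 0")
  if (!all(vapply(object@cestPools, is, logical(1), "Pool")))
    msg <- c(msg, "cestPools must all be Pool objects")
  if (length(object@b0) != 1L || object@b0 <= 0)
    msg <- c(msg, "b0 must be a single number > 0")
  if (length(object@relB1) != 1L || object@relB1 <= 0)
    msg <- c(msg, "relB1 must be a single number > 0")
  if (length(object@db0) != 1L || !is.finite(object@db0))
    msg <- c(msg, "db0 must be a single finite number")
  if (length(msg)) msg else TRUE
})

#' @describeIn CESTEnvironment-class Constructor.
#' @param water,cestPools,mtPool,b0,gammaOver2pi,db0,relB1,extra see slots.
#' @export
CESTEnvironment <- function(water, cestPools = list(), mtPool = NULL,
                            b0 = 3, gammaOver2pi = 42.5764, db0 = 0,
                            relB1 = 1, extra = list()) {
  new("CESTEnvironment", water = water, cestPools = cestPools,
      mtPool = mtPool, b0 = as.numeric(b0),
      gammaOver2pi = as.numeric(gammaOver2pi), db0 = as.numeric(db0),
      relB1 = as.numeric(relB1), extra = extra)
}

#' Bloch-McConnell generator pair
#'
#' The affine ODE dM/dt = A M + C for one constant RF segment.
#'
#' @slot A square rate matrix (1/s).
#' @slot C constant recovery vector (1/s).
#' @export
setClass("GeneratorPair", representation(A = "matrix", C = "numeric"),
         prototype(A = matrix(numeric(0), 0, 0), C = numeric(0)))

setValidity("GeneratorPair", function(object) {
  if (nrow(object@A) != ncol(object@A) ||
      nrow(object@A) != length(object@C))
    "A must be square with nrow equal to length(C)" else TRUE
})

#' @describeIn GeneratorPair-class Constructor. (A slot literally named `C`
#'   cannot be passed through `new()` because it partially matches the
#'   `Class` argument, hence this explicit constructor.)
#' @param A,C see slots.
#' @export
GeneratorPair <- function(A, C) {
  obj <- new("GeneratorPair")
  obj@A <- A
  obj@C <- as.numeric(C)
  validObject(obj)
  obj
}

## ---------------------------------------------------------------------------
## Spectra and fits
## ---------------------------------------------------------------------------

#' Z-spectrum
#'
#' Normalized water signal Z = S_sat / S0 on a strictly increasing ppm grid.
#'
#' @slot offsets numeric, frequency offsets (ppm), strictly increasing.
#' @slot values numeric, Z values (dimensionless).
#' @export
setClass("ZSpectrum", representation(offsets = "numeric", values = "numeric"))

setValidity("ZSpectrum", function(object) {
  msg <- character()
  if (length(object@offsets) != length(object@values))
    msg <- c(msg, "offsets and values must have equal length")
  if (length(object@offsets) && any(diff(object@offsets) <= 0))
    msg <- c(msg, "offsets must be strictly increasing")
  if (any(!is.finite(object@offsets)))
    msg <- c(msg, "offsets must be finite")
  if (length(msg)) msg else TRUE
})

#' @describeIn ZSpectrum-class Constructor; offsets are sorted on input.
#' @param offsets,values see slots.
#' @export
ZSpectrum <- function(offsets, values) {
  o <- order(offsets)
  new("ZSpectrum", offsets = as.numeric(offsets)[o],
      values = as.numeric(values)[o])
}

#' MTR asymmetry spectrum
#'
#' MTRasym(dw) = Z(-dw) - Z(+dw) on a positive ppm grid.
#'
#' @export
setClass("AsymSpectrum", contains = "ZSpectrum")

setValidity("AsymSpectrum", function(object) {
  if (length(object@offsets) && any(object@offsets <= 0))
    "asymmetry offsets must be > 0" else TRUE
})

#' WASABI fit result
#'
#' Absolute B1 amplitude and B0 shift recovered from the Rabi-oscillation
#' pattern of a WASABI Z-spectrum, plus the two nuisance amplitude terms of
#' the fit model and the root-mean-square residual.
#'
#' @slot b1Abs numeric(1), fitted absolute B1 (uT).
#' @slot db0 numeric(1), fitted B0 shift (ppm).
#' @slot c numeric(1), baseline nuisance parameter.
#' @slot d numeric(1), oscillation-depth nuisance parameter.
#' @slot residual numeric(1), RMS fit residual.
#' @export
setClass("WasabiFit", representation(
  b1Abs = "numeric", db0 = "numeric", c = "numeric", d = "numeric",
  residual = "numeric"
))

setValidity("WasabiFit", function(object) {
  msg <- character()
  if (object@b1Abs <= 0) msg <- c(msg, "b1Abs must be > 0")
  if (object@residual < 0) msg <- c(msg, "residual must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Phantom and image stacks
## ---------------------------------------------------------------------------

#' Digital five-tube phantom
#'
#' Integer label image (0 = background, 1..n = tubes), one exchange
#' environment per label, and optional smooth B0/B1 inhomogeneity maps.
#'
#' @slot labels integer matrix of tube labels.
#' @slot environments named list, label as character -> [CESTEnvironment-class].
#' @slot voxelSize numeric(1), in-plane voxel size (mm).
#' @slot db0Map numeric matrix, per-voxel B0 shift (ppm).
#' @slot relB1Map numeric matrix, per-voxel relative B1.
#' @export
setClass("DigitalPhantom", representation(
  labels = "matrix",
  environments = "list",
  voxelSize = "numeric",
  db0Map = "matrix",
  relB1Map = "matrix"
))

setValidity("DigitalPhantom", function(object) {
  msg <- character()
  labs <- sort(unique(as.vector(object@labels)))
  labs <- labs[labs != 0]
  if (!all(as.character(labs) %in% names(object@environments)))
    msg <- c(msg, "every nonzero label needs an environment")
  if (!identical(dim(object@labels), dim(object@db0Map)) ||
      !identical(dim(object@labels), dim(object@relB1Map)))
    msg <- c(msg, "field maps must match the label grid")
  if (length(msg)) msg else TRUE
})

#' Simulated image stack
#'
#' Voxel grid x offsets signal array with the unsaturated reference image
#' and provenance (sequence name, seed, noise level).
#'
#' @slot data numeric array (nx, ny, nOffsets); `NA` outside the object.
#' @slot offsets numeric, ppm per slice of `data`.
#' @slot s0 numeric matrix, unsaturated signal; > 0 inside the object.
#' @slot provenance list (sequence, seed, noiseSd, ...).
#' @export
setClass("ImageStack", representation(
  data = "array",
  offsets = "numeric",
  s0 = "matrix",
  provenance = "list"
))

setValidity("ImageStack", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 3L)
    msg <- c(msg, "data must be a 3-d array")
  else {
    if (dim(object@data)[3] != length(object@offsets))
      msg <- c(msg, "third dimension of data must match length(offsets)")
    if (!identical(dim(object@data)[1:2], dim(object@s0)))
      msg <- c(msg, "s0 must match the voxel grid")
  }
  if (length(msg)) msg else TRUE
})
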