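#' Accessor generics
#'
#' Small accessor generics for the core classes: `offsets()` and `values()`
#' for spectra and sequences, `duration()` and `raster()` for RF shapes,
#' `tSat()` and `dutyCycle()` for timing summaries.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("offsets", function(x) standardGeneric("offsets"))

#' @rdname accessors
#' @export
setGeneric("values", function(x) standardGeneric("values"))

#' @rdname accessors
#' @export
setGeneric("duration", function(x) standardGeneric("duration"))

#' @rdname accessors
#' @export
setGeneric("raster", function(x) standardGeneric("raster"))

#' @rdname accessors
#' @export
setGeneric("tSat", function(x) standardGeneric("tSat"))

#' @rdname accessors
#' @export
setGeneric("dutyCycle", function(x) standardGeneric("dutyCycle"))

#' @rdname accessors
#' @export
setMethod("offsets", "ZSpectrum", function(x) x@offsets)

#' @rdname accessors
#' @export
setMethod("offsets", "CESTSequence", function(x) x@offsets)

#' @rdname accessors
#' @export
setMethod("offsets", "ImageStack", function(x) x@offsets)

#' @rdname accessors
#' @export
setMethod("values", "ZSpectrum", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("duration", "RFShape",
          function(x) x@raster * length(x@amplitude))

#' @rdname accessors
#' @export
setMethod("raster", "RFShape", function(x) x@raster)

#' @rdname accessors
#' @export
setMethod("tSat", "TimingSummary", function(x) x@tSat)

#' @rdname accessors
#' @export
setMethod("dutyCycle", "TimingSummary", function(x) x@dutyCycle)

setMethod("show", "RFShape", function(object) {
  cat(sprintf("RFShape: %d samples, raster %.3g us, duration %.3g ms, peak %.3g uT\n",
              length(object@amplitude), object@raster * 1e6,
              duration(object) * 1e3, max(object@amplitude)))
})

setMethod("show", "PulseTrain", function(object) {
  cat(sprintf("PulseTrain: %d x %.3g ms pulses, t_d %.3g ms\n",
              object@nPulses, duration(object@shape) * 1e3,
              object@interPulseDelay * 1e3))
})

setMethod("show", "TimingSummary", function(object) {
  cat(sprintf("TimingSummary: t_sat %.6g s, duty cycle %.4g%%\n",
              object@tSat, 100 * object@dutyCycle))
})

setMethod("show", "CESTSequence", function(object) {
  cat(sprintf("CESTSequence '%s': %d offsets [%g, %g] ppm, t_rec %.3g s, M0 %s\n",
              object@name, length(object@offsets), min(object@offsets),
              max(object@offsets), object@tRec,
              if (object@m0Policy == "separate") "separate scan"
              else sprintf("far offset %g ppm", object@m0Offset)))
  show(object@train)
})

setMethod("show", "Pool", function(object) {
  cat(sprintf("Pool: f %.4g, T1 %.3g s, T2 %.3g s, k %.4g Hz, dw %.3g ppm\n",
              object@f, object@t1, object@t2, object@k, object@dw))
})

setMethod("show", "CESTEnvironment", function(object) {
  cat(sprintf("CESTEnvironment: B0 %.3g T, %d CEST pool(s), MT %s, db0 %.3g ppm, relB1 %.3g\n",
              object@b0, length(object@cestPools),
              if (is.null(object@mtPool)) "absent" else "present",
              object@db0, object@relB1))
})

setMethod("show", "ZSpectrum", function(object) {
  cat(sprintf("%s: %d offsets [%g, %g] ppm, Z range [%.4g, %.4g]\n",
              class(object), length(object@offsets),
              min(object@offsets), max(object@offsets),
              min(object@values), max(object@values)))
})

setMethod("show", "WasabiFit", function(object) {
  cat(sprintf("WasabiFit: B1 %.4g uT, dB0 %.4g ppm, c %.3g, d %.3g, RMS residual %.3g\n",
              object@b1Abs, object@db0, object@c, object@d, object@residual))
})

setMethod("show", "DigitalPhantom", function(object) {
  cat(sprintf("DigitalPhantom: %d x %d grid, %d tubes, voxel %.3g mm\n",
              nrow(object@labels), ncol(object@labels),
              length(object@environments), object@voxelSize))
})

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@data)
  cat(sprintf("ImageStack: %d x %d voxels, %d offsets, sequence '%s'\n",
              d[1], d[2], d[3],
              if (is.null(object@provenance$sequence)) "?"
              else object@provenance$sequence))
})

#' Convert a Z-spectrum to a data.frame
#'
#' @param x a [ZSpectrum-class].
#' @param ... unused.
#' @return data.frame with columns `offset_ppm` and `value`.
#' @export
as.data.frame.ZSpectrum <- function(x, ...) {
  data.frame(offset_ppm = x@offsets, value = x@values)
}
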