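## Z-spectrum evaluation: normalization, interpolation, MTR asymmetry,
## B0 correction, WASABI field fitting, ROI and map reductions.

#' Normalize raw signals into a Z-spectrum
#'
#' @param raw signal per offset.
#' @param offsets frequency offsets (ppm), same length as `raw`.
#' @param s0 unsaturated reference signal, > 0 (scalar or per offset).
#' @return a [ZSpectrum-class] with `values = raw / s0`, sorted by offset.
#' @export
normalizeSpectrum <- function(raw, offsets, s0) {
  if (any(!is.finite(s0)) || any(s0 <= 0)) stop("s0 must be > 0")
  if (length(raw) != length(offsets))
    stop("raw and offsets must have equal length")
  ZSpectrum(offsets, raw / s0)
}

## robust noise-scale estimate from second differences of the sampled curve
.noiseScale <- function(v) {
  if (length(v) < 3L) return(0)
  d2 <- diff(v, differences = 2L)
  sqrt(mean(d2^2) / 6)
}

#' Interpolate or smooth a Z-spectrum onto a new grid
#'
#' `"linear"` reproduces the sampled values exactly at the original nodes
#' and interpolates piecewise-linearly between them. `"smoothing_spline"`
#' fits a cubic smoothing spline whose residual sum of squares at the nodes
#' stays within the budget `n * s^2`, where `s` is a noise scale estimated
#' from second differences; the smoothing parameter is reduced until the
#' budget holds, so genuine spectral structure is retained while
#' sample-to-sample noise is suppressed.
#'
#' @param z a [ZSpectrum-class].
#' @param grid target offsets (ppm) inside the sampled range.
#' @param method `"linear"` or `"smoothing_spline"`.
#' @return a [ZSpectrum-class] on `grid`.
#' @export
interpolateSpectrum <- function(z, grid,
                                method = c("linear", "smoothing_spline")) {
  method <- match.arg(method)
  stopifnot(is(z, "ZSpectrum"))
  x <- z@offsets; v <- z@values
  if (min(grid) < min(x) || max(grid) > max(x))
    stop("grid requests extrapolation beyond the sampled offset range")
  if (method == "linear") {
    out <- stats::approx(x, v, xout = sort(grid))$y
    return(ZSpectrum(sort(grid), out))
  }
  n <- length(x)
  # expected residual sum of squares of a noise-suppressing fit
  budget <- n * .noiseScale(v)^2
  rssAt <- function(spar) {
    fit <- stats::smooth.spline(x, v, spar = spar, cv = FALSE)
    sum((stats::predict(fit, x)$y - v)^2)
  }
  fit <- stats::smooth.spline(x, v, cv = FALSE)  # GCV choice
  if (sum((stats::predict(fit, x)$y - v)^2) > budget) {
    lo <- -1.5; hi <- fit$spar
    for (i in 1:30) {
      mid <- (lo + hi) / 2
      if (rssAt(mid) > budget) hi <- mid else lo <- mid
    }
    fit <- stats::smooth.spline(x, v, spar = lo, cv = FALSE)
  }
  ZSpectrum(sort(grid), stats::predict(fit, sort(grid))$y)
}

#' MTR asymmetry spectrum
#'
#' MTRasym(dw) = Z(-dw) - Z(+dw) for dw > 0, so a CEST pool resonating at
#' positive ppm produces a positive peak. Mirrored offsets that were not
#' sampled are obtained by linear interpolation.
#'
#' @param z a [ZSpectrum-class] covering a symmetric range around 0.
#' @return an [AsymSpectrum-class] on the sampled positive offsets.
#' @export
mtrAsym <- function(z) {
  stopifnot(is(z, "ZSpectrum"))
  x <- z@offsets
  pos <- x[x > 0]
  if (!length(pos) || min(x) >= 0)
    stop("spectrum must cover both sides of 0 ppm")
  pos <- pos[-pos >= min(x)]
  if (!length(pos))
    stop("no positive offsets with a mirrored counterpart in range")
  zp <- stats::approx(x, z@values, xout = pos)$y
  zm <- stats::approx(x, z@values, xout = -pos)$y
  new("AsymSpectrum", offsets = pos, values = zm - zp)
}

#' Shift-correct a Z-spectrum for a known B0 offset
#'
#' Re-interpolates the measured values at `offsets + db0` and returns them
#' on the nominal grid, undoing a static field shift of `db0` ppm.
#'
#' @param z a [ZSpectrum-class].
#' @param db0 field shift (ppm); must be smaller than the sampled range.
#' @return a corrected [ZSpectrum-class] on the nominal grid restricted to
#'   offsets whose shifted lookup stays in range.
#' @export
b0Correct <- function(z, db0) {
  stopifnot(is(z, "ZSpectrum"))
  x <- z@offsets
  if (abs(db0) > (max(x) - min(x)) / 2)
    stop("db0 shift exceeds half the sampled range")
  keep <- (x + db0) >= min(x) & (x + db0) <= max(x)
  if (!any(keep)) stop("db0 shift leaves no offsets in range")
  ZSpectrum(x[keep], stats::approx(x, z@values, xout = x[keep] + db0)$y)
}

#' Fit the WASABI field-mapping model to a Z-spectrum
#'
#' Least-squares fit of the off-resonant Rabi model
#' `Z(dw) = | c - d * (w1^2 / weff^2) * sin^2(weff * tp / 2) |` with
#' `w1 = 2 pi gamma B1` and `weff^2 = w1^2 + (dw - db0)^2` (angular
#' frequencies), returning the absolute B1 and the water-frequency shift
#' db0. The two nuisance amplitudes are bounded (`c` in [0.5, 1.5], `d` in
#' [0.1, 3]) and a 5 x 5 multi-start grid over (B1, db0) guards against
#' local minima of the oscillatory objective.
#'
#' @param z a [ZSpectrum-class] sampled densely enough to resolve the Rabi
#'   oscillations.
#' @param tp pulse duration (s).
#' @param b1Nominal nominal B1 (uT), centre of the multi-start grid.
#' @param f0 scanner frequency per ppm (Hz/ppm), i.e. `gamma * B0`;
#'   default 3 T protons.
#' @param gammaOver2pi gyromagnetic ratio / 2 pi (MHz/T).
#' @return a [WasabiFit-class].
#' @export
wasabiFit <- function(z, tp = 5e-3, b1Nominal = 3.7, f0 = 42.5764 * 3,
                      gammaOver2pi = 42.5764) {
  stopifnot(is(z, "ZSpectrum"))
  x <- z@offsets; v <- z@values
  model <- function(par) {
    w1 <- 2 * pi * gammaOver2pi * par[1]
    dwr <- 2 * pi * f0 * (x - par[2])
    weff2 <- w1^2 + dwr^2
    abs(par[3] - par[4] * (w1^2 / weff2) * sin(sqrt(weff2) * tp / 2)^2)
  }
  sse <- function(par) sum((model(par) - v)^2)
  lower <- c(0.2 * b1Nominal, min(x) / 2, 0.5, 0.1)
  upper <- c(3.0 * b1Nominal, max(x) / 2, 1.5, 3.0)
  best <- NULL
  for (b1s in b1Nominal * seq(0.6, 1.4, length.out = 5)) {
    for (d0s in seq(-0.3, 0.3, length.out = 5)) {
      fit <- try(stats::optim(c(b1s, d0s, 1, 2), sse, method = "L-BFGS-B",
                              lower = lower, upper = upper,
                              control = list(maxit = 500)), silent = TRUE)
      if (inherits(fit, "try-error")) next
      if (is.null(best) || fit$value < best$value) best <- fit
    }
  }
  if (is.null(best))
    stop("WASABI fit failed to converge from any start")
  res <- sqrt(best$value / length(x))
  new("WasabiFit", b1Abs = best$par[1], db0 = best$par[2],
      c = best$par[3], d = best$par[4], residual = res)
}

#' Reduce an image stack over a region of interest
#'
#' @param stack an [ImageStack-class].
#' @param mask logical matrix on the voxel grid.
#' @return list with `mean` (a [ZSpectrum-class] of ROI-mean Z values) and
#'   `sd` (per-offset standard deviation over the masked voxels).
#' @export
roiReduce <- function(stack, mask) {
  stopifnot(is(stack, "ImageStack"))
  if (!identical(dim(mask), dim(stack@s0)))
    stop("mask must match the voxel grid")
  if (!any(mask)) stop("empty mask")
  d <- dim(stack@data)
  flat <- matrix(stack@data, d[1] * d[2], d[3])
  zmat <- flat[as.vector(mask), , drop = FALSE] /
    stack@s0[as.vector(mask)]
  spread <- if (nrow(zmat) > 1L) apply(zmat, 2, stats::sd)
            else numeric(ncol(zmat))
  list(mean = ZSpectrum(stack@offsets, colMeans(zmat)), sd = spread)
}

## fit each distinct voxel spectrum once; identical spectra (noiseless
## phantom tubes) share one computation
.uniqueVoxelApply <- function(zmat, fun) {
  keys <- apply(zmat, 1, function(r) paste(signif(r, 12), collapse = ","))
  uk <- !duplicated(keys)
  vals <- vapply(which(uk), function(i) fun(zmat[i, ]), numeric(1))
  vals[match(keys, keys[uk])]
}

#' Voxelwise parametric map from an image stack
#'
#' Applies [mtrAsym()] (`kind = "mtrasym"`, evaluated at `ppm`) or
#' [wasabiFit()] (`kind = "b0"` or `"b1"`) to every foreground voxel.
#' Background voxels (s0 <= 0 or non-finite spectra) are `NA`.
#'
#' @param stack an [ImageStack-class].
#' @param kind `"mtrasym"`, `"b0"` or `"b1"`.
#' @param ppm evaluation offset for `"mtrasym"` maps.
#' @param tp,b1Nominal,f0 passed to [wasabiFit()] for field maps.
#' @return numeric matrix on the voxel grid.
#' @export
parametricMap <- function(stack, kind = c("mtrasym", "b0", "b1"),
                          ppm = 3.0, tp = 5e-3, b1Nominal = 3.7,
                          f0 = 42.5764 * 3) {
  kind <- match.arg(kind)
  stopifnot(is(stack, "ImageStack"))
  d <- dim(stack@data)
  flat <- matrix(stack@data, d[1] * d[2], d[3])
  ok <- as.vector(is.finite(stack@s0) & stack@s0 > 0) &
    apply(flat, 1, function(r) all(is.finite(r)))
  out <- rep(NA_real_, d[1] * d[2])
  if (any(ok)) {
    zmat <- flat[ok, , drop = FALSE] / stack@s0[ok]
    fun <- switch(kind,
      mtrasym = function(zv) {
        a <- mtrAsym(ZSpectrum(stack@offsets, zv))
        if (length(a@offsets) == 1L)
          return(if (abs(a@offsets - ppm) < 1e-9) a@values else NA_real_)
        stats::approx(a@offsets, a@values, xout = ppm)$y
      },
      b0 = function(zv)
        wasabiFit(ZSpectrum(stack@offsets, zv), tp = tp,
                  b1Nominal = b1Nominal, f0 = f0)@db0,
      b1 = function(zv)
        wasabiFit(ZSpectrum(stack@offsets, zv), tp = tp,
                  b1Nominal = b1Nominal, f0 = f0)@b1Abs)
    out[ok] <- .uniqueVoxelApply(zmat, fun)
  }
  matrix(out, d[1], d[2])
}
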