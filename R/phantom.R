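## Synthetic digital five-tube phantom and per-voxel simulated image stacks.

#' Build the digital five-tube phantom
#'
#' Five disjoint circular tubes on a ring, labelled 1..5 and mapped to
#' [phantomEnvironments()] (L-arginine 20/27/40/60/70 mM, agarose MT pool
#' in tubes 3-5). Optional smooth low-order polynomial B0/B1 field maps
#' emulate scanner inhomogeneity; by default both fields are homogeneous.
#' The disc-on-a-ring geometry is a synthetic stand-in, not a model of any
#' measured phantom's layout.
#'
#' @param grid grid side length (voxels).
#' @param tubeRadius tube radius (voxels).
#' @param fieldInhomogeneity `NULL` for homogeneous fields, or a list with
#'   elements `db0` (peak B0 shift, ppm) and/or `relB1` (peak relative B1
#'   deviation); both vary linearly across the grid.
#' @param voxelSize voxel size (mm).
#' @param b0 static field (T).
#' @return a [DigitalPhantom-class].
#' @export
makeDigitalPhantom <- function(grid = 64L, tubeRadius = 7,
                               fieldInhomogeneity = NULL,
                               voxelSize = 1, b0 = 3) {
  grid <- as.integer(grid)
  envs <- phantomEnvironments(b0 = b0)
  nT <- length(envs)
  cx <- (grid + 1) / 2
  ringR <- grid * 0.3
  ang <- pi / 2 + 2 * pi * (seq_len(nT) - 1) / nT
  centers <- cbind(cx + ringR * cos(ang), cx + ringR * sin(ang))
  # disjointness: chord between adjacent centres must exceed 2 r
  minChord <- 2 * ringR * sin(pi / nT)
  if (minChord <= 2 * tubeRadius || ringR + tubeRadius > cx)
    stop("tubes overlap or leave the grid; enlarge grid or shrink tubeRadius")
  xs <- matrix(seq_len(grid), grid, grid)
  ys <- matrix(seq_len(grid), grid, grid, byrow = TRUE)
  labels <- matrix(0L, grid, grid)
  for (i in seq_len(nT)) {
    inside <- (xs - centers[i, 1])^2 + (ys - centers[i, 2])^2 <= tubeRadius^2
    labels[inside] <- i
  }
  u <- 2 * (xs - cx) / grid   # [-1, 1] across the grid
  v <- 2 * (ys - cx) / grid
  db0Map <- matrix(0, grid, grid)
  relB1Map <- matrix(1, grid, grid)
  if (!is.null(fieldInhomogeneity)) {
    if (!is.null(fieldInhomogeneity$db0))
      db0Map <- fieldInhomogeneity$db0 * u
    if (!is.null(fieldInhomogeneity$relB1))
      relB1Map <- 1 + fieldInhomogeneity$relB1 * v
  }
  new("DigitalPhantom", labels = labels, environments = envs,
      voxelSize = as.numeric(voxelSize), db0Map = db0Map,
      relB1Map = relB1Map)
}

#' Simulate an image stack over a digital phantom
#'
#' Runs [simulateZspectrum()] once per distinct (environment, db0, relB1)
#' combination -- field maps are quantized (db0 to 0.005 ppm, relB1 to
#' 0.5%) so homogeneous regions share a single simulation -- and fills
#' every voxel with its tube's spectrum. Additive Gaussian noise of
#' standard deviation `noiseSd` (on the normalized signal scale) is then
#' applied independently per voxel and offset.
#'
#' @param seq a [CESTSequence-class].
#' @param phantom a [DigitalPhantom-class].
#' @param noiseSd Gaussian noise standard deviation (fraction of S0).
#' @param seed integer RNG seed for the noise.
#' @param maxDt propagation step passed to [simulateZspectrum()].
#' @return an [ImageStack-class]; background voxels are `NA` with s0 = 0.
#' @export
simulateStack <- function(seq, phantom, noiseSd = 0, seed = 1L,
                          maxDt = 1e-4) {
  stopifnot(is(seq, "CESTSequence"), is(phantom, "DigitalPhantom"))
  if (noiseSd < 0) stop("noiseSd must be >= 0")
  labs <- phantom@labels
  d <- dim(labs)
  nOff <- length(seq@offsets)
  db0q <- round(phantom@db0Map / 0.005) * 0.005
  b1q <- round(phantom@relB1Map / 0.005) * 0.005
  inside <- labs != 0L
  key <- ifelse(inside,
                sprintf("%d|%.3f|%.3f", labs, db0q, b1q), NA_character_)
  data <- array(NA_real_, c(d, nOff))
  s0 <- matrix(0, d[1], d[2])
  ord <- order(seq@offsets)
  for (k in unique(key[inside])) {
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    env <- phantom@environments[[parts[1]]]
    if (is.null(env)) stop("no environment for label ", parts[1])
    env@db0 <- env@db0 + as.numeric(parts[2])
    env@relB1 <- env@relB1 * as.numeric(parts[3])
    z <- simulateZspectrum(seq, env, maxDt = maxDt)
    # ZSpectrum is offset-sorted; scatter back into sequence order
    zseq <- numeric(nOff)
    zseq[ord] <- z@values
    vox <- which(!is.na(key) & key == k)
    for (j in seq_len(nOff))
      data[vox + (j - 1L) * d[1] * d[2]] <- zseq[j]
    s0[vox] <- 1
  }
  if (noiseSd > 0) {
    set.seed(as.integer(seed))
    noise <- array(stats::rnorm(prod(d) * nOff, sd = noiseSd), c(d, nOff))
    data <- data + noise * rep(as.numeric(inside), nOff)
  }
  new("ImageStack", data = data, offsets = seq@offsets, s0 = s0,
      provenance = list(sequence = seq@name, seed = as.integer(seed),
                        noiseSd = noiseSd, maxDt = maxDt))
}

#' Write an image stack to disk
#'
#' Writes a directory holding `data.nii.gz` and `s0.nii.gz` (double
#' precision NIfTI), an `offsets.txt` sidecar (one ppm value per line) and
#' a `provenance.yaml`.
#'
#' @param stack an [ImageStack-class].
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  RNifti::writeNifti(RNifti::asNifti(stack@data),
                     file.path(path, "data.nii.gz"), datatype = "double")
  RNifti::writeNifti(RNifti::asNifti(stack@s0),
                     file.path(path, "s0.nii.gz"), datatype = "double")
  writeLines(sprintf("%.12g", stack@offsets),
             file.path(path, "offsets.txt"))
  writeLines(yaml::as.yaml(stack@provenance, precision = 15L),
             file.path(path, "provenance.yaml"))
  invisible(path)
}

#' Read an image stack written by [writeStack()]
#'
#' @param path stack directory.
#' @return an [ImageStack-class].
#' @export
readStack <- function(path) {
  dataFile <- file.path(path, "data.nii.gz")
  offFile <- file.path(path, "offsets.txt")
  if (!file.exists(dataFile)) stop("missing data.nii.gz in ", path)
  if (!file.exists(offFile)) stop("missing offsets.txt sidecar in ", path)
  img <- RNifti::readNifti(dataFile)
  data <- array(as.numeric(img), dim(img))
  s0 <- RNifti::readNifti(file.path(path, "s0.nii.gz"))
  s0 <- matrix(as.numeric(s0), dim(s0)[1], dim(s0)[2])
  offs <- as.numeric(readLines(offFile))
  if (dim(data)[3] != length(offs))
    stop("offsets.txt does not match the data depth")
  provFile <- file.path(path, "provenance.yaml")
  prov <- if (file.exists(provFile)) yaml::read_yaml(provFile) else list()
  new("ImageStack", data = data, offsets = offs, s0 = s0,
      provenance = prov)
}
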