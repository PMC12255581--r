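## Preparation -> simulation -> evaluation pipeline driven by one yaml
## config, plus a sequence-vs-environments comparison table.

.builtinSequence <- function(spec) {
  if (is(spec, "CESTSequence")) return(spec)
  switch(spec,
         aptw3t = buildAPTw3T(),
         wasabi = buildWASABI(),
         {
           if (!file.exists(spec))
             stop("sequence '", spec, "' is neither built-in nor a file")
           readSeq(spec)
         })
}

.resolveEnvironment <- function(spec) {
  if (is(spec, "CESTEnvironment")) return(spec)
  if (is.list(spec) && !is.null(spec$larginine_mM))
    return(larginineEnvironment(spec$larginine_mM))
  if (is.character(spec) && file.exists(spec))
    return(loadEnvironment(spec))
  stop("cannot resolve environment spec")
}

.knownSteps <- c("zspec", "mtrasym", "wasabi", "maps")

#' Run the preparation / simulation / evaluation pipeline
#'
#' Executes the stages named in `cfg$steps` in order and writes each
#' artifact (TSV spectra, TSV maps, the simulated stack) into
#' `cfg$outdir`, together with a yaml manifest listing every file with its
#' md5 hash, the seed and the package version. Identical configs produce
#' identical manifests.
#'
#' Config fields: `sequence` (`"aptw3t"`, `"wasabi"` or a .seq path),
#' either `environment` (yaml path or `list(larginine_mM = ...)`) or
#' `phantom: true`, `steps` (subset of `zspec`, `mtrasym`, `wasabi`,
#' `maps`), `outdir`, and optional `seed`, `max_dt`, `noise_sd`.
#'
#' @param cfg a list, or the path of a yaml config file.
#' @return the manifest, invisibly (named list).
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- yaml::read_yaml(cfg)
  steps <- cfg$steps
  if (is.null(steps) || !length(steps)) stop("config error: no steps given")
  bad <- setdiff(unlist(steps), .knownSteps)
  if (length(bad))
    stop("config error: unknown step(s) ", paste(bad, collapse = ", "))
  if (is.null(cfg$outdir)) stop("config error: outdir missing")
  if (is.null(cfg$sequence)) stop("config error: sequence missing")
  usePhantom <- isTRUE(cfg$phantom)
  if (!usePhantom && is.null(cfg$environment))
    stop("config error: need 'environment' or 'phantom: true'")
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  maxDt <- if (is.null(cfg$max_dt)) 1e-4 else as.numeric(cfg$max_dt)
  noiseSd <- if (is.null(cfg$noise_sd)) 0 else as.numeric(cfg$noise_sd)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  sq <- .builtinSequence(cfg$sequence)
  files <- character()
  emitTsv <- function(df, name) {
    path <- file.path(cfg$outdir, name)
    utils::write.table(format(df, digits = 12, trim = TRUE), path,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
    path
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    message(sprintf("[cestkit] stage %-8s %6.1f s", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }
  z <- NULL
  stk <- NULL
  if (usePhantom) {
    ph <- makeDigitalPhantom()
    stk <- stage("simulate",
                 simulateStack(sq, ph, noiseSd = noiseSd, seed = seed,
                               maxDt = maxDt))
    stackDir <- file.path(cfg$outdir, "stack")
    writeStack(stk, stackDir)
    files <- c(files, list.files(stackDir, full.names = TRUE))
    roi <- roiReduce(stk, ph@labels == 1L)
    z <- roi$mean
  } else {
    env <- .resolveEnvironment(cfg$environment)
    z <- stage("simulate", simulateZspectrum(sq, env, maxDt = maxDt))
  }
  for (st in unlist(steps)) {
    if (st == "zspec") {
      emitTsv(data.frame(offset_ppm = z@offsets, Z = z@values), "zspec.tsv")
    } else if (st == "mtrasym") {
      a <- stage("mtrasym", mtrAsym(z))
      emitTsv(data.frame(offset_ppm = a@offsets, MTRasym = a@values),
              "asym.tsv")
    } else if (st == "wasabi") {
      fit <- stage("wasabi", wasabiFit(z))
      emitTsv(data.frame(b1_uT = fit@b1Abs, db0_ppm = fit@db0,
                         c = fit@c, d = fit@d, rms = fit@residual),
              "wasabi.tsv")
    } else if (st == "maps") {
      if (is.null(stk)) stop("stage 'maps' failed: needs 'phantom: true'",
                             call. = FALSE)
      if (sq@name == "WASABI") {
        b0m <- stage("maps", parametricMap(stk, "b0"))
        b1m <- parametricMap(stk, "b1")
        emitTsv(as.data.frame(b0m), "b0_map.tsv")
        emitTsv(as.data.frame(b1m), "b1_map.tsv")
      } else {
        m <- stage("maps", parametricMap(stk, "mtrasym", ppm = 3.0))
        emitTsv(as.data.frame(m), "mtrasym_map.tsv")
      }
    }
  }
  manifest <- list(
    sequence = sq@name,
    seed = seed,
    noise_sd = noiseSd,
    max_dt = maxDt,
    package_version = as.character(utils::packageVersion("cestkit")),
    files = lapply(sort(files), function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
  writeLines(yaml::as.yaml(manifest, precision = 15L),
             file.path(cfg$outdir, "manifest.yaml"))
  invisible(manifest)
}

#' Compare one sequence across several environments
#'
#' Simulates the sequence in every environment and tabulates where the
#' MTRasym curve peaks and how high the peak is.
#'
#' @param seq a [CESTSequence-class] (or built-in name).
#' @param envs named list of [CESTEnvironment-class] objects.
#' @param maxDt propagation step (s).
#' @return data.frame with columns `environment`, `argmax_ppm`,
#'   `max_asym`.
#' @export
compareEnvironments <- function(seq, envs, maxDt = 1e-4) {
  if (is.character(seq)) seq <- .builtinSequence(seq)
  if (!length(envs)) stop("need at least one environment")
  nms <- names(envs)
  if (is.null(nms)) nms <- paste0("env", seq_along(envs))
  rows <- lapply(seq_along(envs), function(i) {
    z <- simulateZspectrum(seq, envs[[i]], maxDt = maxDt)
    a <- mtrAsym(z)
    if (!length(a@offsets)) stop("empty evaluation grid")
    j <- which.max(a@values)
    data.frame(environment = nms[i], argmax_ppm = a@offsets[j],
               max_asym = a@values[j])
  })
  do.call(rbind, rows)
}
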