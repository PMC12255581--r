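## Portable text serialization of CEST sequences.
##
## Format: a [DEFINITIONS] section of key = value lines (sequence-level
## parameters) followed by a [SHAPE] section holding the raster and one
## "amplitude_uT phase_rad" pair per sample. Values are written with 12
## significant digits, ample for the 1e-9 round-trip contract.

.fmt <- function(x) sprintf("%.12g", x)

#' Write a CEST sequence as portable text
#'
#' @param seq a [CESTSequence-class].
#' @param file path or connection to write to.
#' @return `file`, invisibly.
#' @seealso [readSeq()]
#' @export
writeSeq <- function(seq, file) {
  stopifnot(is(seq, "CESTSequence"))
  tr <- seq@train
  sh <- tr@shape
  lines <- c(
    "# cestkit sequence v1",
    "[DEFINITIONS]",
    paste0("name = ", seq@name),
    paste0("offsets_ppm = ", paste(.fmt(seq@offsets), collapse = " ")),
    paste0("trec_s = ", .fmt(seq@tRec)),
    paste0("tp_s = ", .fmt(duration(sh))),
    paste0("td_s = ", .fmt(tr@interPulseDelay)),
    paste0("n_pulses = ", tr@nPulses),
    paste0("b1_rms_uT = ", .fmt(sqrt(mean(sh@amplitude^2)))),
    "shape = sampled",
    paste0("pulse_phases_rad = ", paste(.fmt(tr@phases), collapse = " ")),
    paste0("m0_policy = ",
           if (seq@m0Policy == "separate") "separate"
           else paste("far_offset", .fmt(seq@m0Offset))),
    "[SHAPE]",
    paste0("raster_s = ", .fmt(sh@raster)),
    paste(.fmt(sh@amplitude), .fmt(sh@phase))
  )
  writeLines(lines, file)
  invisible(file)
}

.parseError <- function(lineNo, line, why) {
  stop(sprintf("sequence parse error at line %d ('%s'): %s",
               lineNo, substr(line, 1, 40), why), call. = FALSE)
}

#' Read a CEST sequence from portable text
#'
#' @param file path or connection written by [writeSeq()].
#' @return a [CESTSequence-class].
#' @export
readSeq <- function(file) {
  lines <- readLines(file)
  lines <- sub("\\s+$", "", lines)
  keep <- !grepl("^\\s*(#|$)", lines)
  idx <- which(keep)
  section <- ""
  defs <- list()
  amps <- numeric()
  phs <- numeric()
  rasterS <- NA_real_
  for (i in idx) {
    ln <- trimws(lines[i])
    if (grepl("^\\[", ln)) {
      if (!ln %in% c("[DEFINITIONS]", "[SHAPE]"))
        .parseError(i, ln, "unknown section")
      section <- ln
      next
    }
    if (section == "[DEFINITIONS]") {
      kv <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*=\\s*(.*)$", ln))[[1]]
      if (length(kv) != 3) .parseError(i, ln, "expected 'key = value'")
      defs[[kv[2]]] <- kv[3]
    } else if (section == "[SHAPE]") {
      if (grepl("^raster_s", ln)) {
        rasterS <- suppressWarnings(as.numeric(sub("^raster_s\\s*=\\s*", "", ln)))
        if (!is.finite(rasterS)) .parseError(i, ln, "bad raster_s value")
      } else {
        v <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
        if (length(v) != 2 || any(!is.finite(v)))
          .parseError(i, ln, "expected 'amplitude phase' sample pair")
        amps <- c(amps, v[1])
        phs <- c(phs, v[2])
      }
    } else {
      .parseError(i, ln, "content before any section header")
    }
  }
  need <- c("offsets_ppm", "trec_s", "td_s", "n_pulses", "m0_policy")
  miss <- setdiff(need, names(defs))
  if (length(miss))
    stop("sequence file incomplete: missing ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!length(amps)) stop("sequence file incomplete: no [SHAPE] samples",
                          call. = FALSE)
  if (!is.finite(rasterS)) stop("sequence file incomplete: missing raster_s",
                                call. = FALSE)
  num <- function(key) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(defs[[key]]), "\\s+")[[1]]))
    if (any(!is.finite(v))) stop("bad numeric value for ", key, call. = FALSE)
    v
  }
  nP <- as.integer(num("n_pulses"))
  phases <- if (!is.null(defs$pulse_phases_rad)) num("pulse_phases_rad")
            else rep(0, nP)
  pol <- trimws(defs$m0_policy)
  if (pol == "separate") {
    m0Policy <- "separate"; m0Offset <- NA_real_
  } else if (grepl("^far_offset\\s", pol)) {
    m0Policy <- "far-offset"
    m0Offset <- suppressWarnings(as.numeric(sub("^far_offset\\s+", "", pol)))
    if (!is.finite(m0Offset)) stop("bad far_offset value", call. = FALSE)
  } else stop("unknown m0_policy '", pol, "'", call. = FALSE)
  shape <- RFShape(amps, phs, rasterS)
  train <- PulseTrain(shape, nP, num("td_s"), phases)
  CESTSequence(num("offsets_ppm"), train, tRec = num("trec_s"),
               m0Policy = m0Policy, m0Offset = m0Offset,
               name = if (is.null(defs$name)) "cest" else defs$name)
}
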