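## Exchange environments: canned phantom environments and the yaml dialect
## used by public simulation-parameter libraries (water_pool / cest_pool /
## mt_pool blocks plus b0, gamma, rel_b1, db0).

#' L-arginine exchange environment
#'
#' Aqueous L-arginine at acidic pH on a 3 T scanner: water with
#' T1 = 1500 ms and T2 = 1000 ms and one guanidinium CEST pool at
#' +3.0 ppm exchanging at 350 Hz. The pool fraction follows
#' f = nH * c / 111000 mM with nH = 3 labile guanidinium protons relative
#' to the 2 x 55.5 M water proton concentration.
#'
#' @param conc L-arginine concentration (mM), > 0.
#' @param b0 static field (T).
#' @return a [CESTEnvironment-class].
#' @examples
#' env <- larginineEnvironment(20)
#' env@cestPools$arginine@f  # 5.405e-4
#' @export
larginineEnvironment <- function(conc, b0 = 3) {
  if (!is.finite(conc) || conc <= 0) stop("conc must be > 0")
  pool <- Pool(f = 3 * conc / 111000, t1 = 1.5, t2 = 0.1, k = 350, dw = 3.0)
  CESTEnvironment(water = Pool(1, 1.5, 1.0),
                  cestPools = list(arginine = pool),
                  b0 = b0)
}

#' Agarose semisolid MT pool
#'
#' Default macromolecular pool for a 2% agarose gel: fraction 0.05,
#' T1 = 1 s, T2 = 10 us, exchange 30 Hz, centred on water, Lorentzian
#' absorption lineshape. These are package defaults for gel phantoms and
#' can be overridden via yaml.
#'
#' @return an [MTPool-class].
#' @export
agaroseMTPool <- function() {
  MTPool(f = 0.05, t1 = 1, t2 = 1e-5, k = 30, dw = 0,
         lineshape = "lorentzian")
}

#' Five-tube phantom environments
#'
#' The exchange environments of the synthetic five-tube phantom: L-arginine
#' concentrations 20/27/40/60/70 mM at pH ~4 (exchange rate 350 Hz), water
#' T1 = 1500 ms and T2 = 1000 ms everywhere. Tubes 1-2 (cyst-like, 0%
#' agarose) have no MT pool; tubes 3-5 (tissue/tumor-like, 2% agarose) add
#' the semisolid agarose MT pool, the gel's dominant effect on the
#' Z-spectrum baseline.
#'
#' @param b0 static field (T).
#' @return named list of 5 [CESTEnvironment-class] objects
#'   (`"1"` ... `"5"`).
#' @export
phantomEnvironments <- function(b0 = 3) {
  conc <- c(20, 27, 40, 60, 70)
  agar <- c(FALSE, FALSE, TRUE, TRUE, TRUE)
  envs <- lapply(seq_along(conc), function(i) {
    env <- larginineEnvironment(conc[i], b0 = b0)
    if (agar[i]) env@mtPool <- agaroseMTPool()
    env
  })
  names(envs) <- as.character(seq_along(conc))
  envs
}

## ---------------------------------------------------------------------------
## yaml dialect
## ---------------------------------------------------------------------------

.poolFromYaml <- function(lst, where, needK = TRUE) {
  need <- c("f", "t1", "t2", if (needK) c("k", "dw"))
  for (key in need)
    if (is.null(lst[[key]]))
      stop(sprintf("%s.%s missing", where, key), call. = FALSE)
  vals <- lapply(c("f", "t1", "t2", "k", "dw"), function(key) {
    v <- lst[[key]]
    if (is.null(v)) return(0)
    if (!is.numeric(v) || !is.finite(v))
      stop(sprintf("%s.%s must be a finite number", where, key),
           call. = FALSE)
    v
  })
  names(vals) <- c("f", "t1", "t2", "k", "dw")
  vals
}

#' Load an exchange environment from yaml
#'
#' Reads the sim-library style yaml dialect: a `water_pool` block (f, t1,
#' t2), an optional `cest_pool` block of named pools (f, t1, t2, k, dw), an
#' optional `mt_pool` block (pool fields plus `lineshape`), and the scalars
#' `b0`, `gamma`, `rel_b1`, `db0`. Unknown top-level keys are preserved and
#' written back by [saveEnvironment()].
#'
#' @param source a file path or a single yaml string.
#' @return a [CESTEnvironment-class].
#' @export
loadEnvironment <- function(source) {
  y <- if (length(source) == 1L && !grepl("\n", source) &&
           file.exists(source)) yaml::read_yaml(source)
       else yaml::yaml.load(paste(source, collapse = "\n"))
  if (!is.list(y)) stop("environment yaml must be a mapping", call. = FALSE)
  if (is.null(y$water_pool)) stop("water_pool missing", call. = FALSE)
  w <- .poolFromYaml(y$water_pool, "water_pool", needK = FALSE)
  water <- Pool(f = 1, t1 = w$t1, t2 = w$t2)
  cest <- list()
  if (!is.null(y$cest_pool)) {
    cest <- lapply(names(y$cest_pool), function(nm) {
      p <- .poolFromYaml(y$cest_pool[[nm]], paste0("cest_pool.", nm))
      if (p$k < 0) stop("cest_pool.", nm, ".k must be >= 0", call. = FALSE)
      Pool(p$f, p$t1, p$t2, p$k, p$dw)
    })
    names(cest) <- names(y$cest_pool)
  }
  mt <- NULL
  if (!is.null(y$mt_pool)) {
    p <- .poolFromYaml(y$mt_pool, "mt_pool")
    ls <- if (is.null(y$mt_pool$lineshape)) "lorentzian" else y$mt_pool$lineshape
    mt <- MTPool(p$f, p$t1, p$t2, p$k, p$dw, lineshape = ls)
  }
  known <- c("water_pool", "cest_pool", "mt_pool", "b0", "gamma",
             "rel_b1", "db0")
  CESTEnvironment(
    water = water, cestPools = cest, mtPool = mt,
    b0 = if (is.null(y$b0)) 3 else y$b0,
    gammaOver2pi = if (is.null(y$gamma)) 42.5764 else y$gamma,
    db0 = if (is.null(y$db0)) 0 else y$db0,
    relB1 = if (is.null(y$rel_b1)) 1 else y$rel_b1,
    extra = y[setdiff(names(y), known)])
}

## shortest decimal representation that reparses to the identical double
.verbatimNumber <- function(v) {
  s <- sprintf("%.15g", v)
  long <- s != "0" & suppressWarnings(as.numeric(s)) != v
  s[long] <- sprintf("%.17g", v[long])
  # YAML 1.1 floats need a dot: "1e-05" would parse as a string
  fix <- grepl("e", s, fixed = TRUE) & !grepl(".", s, fixed = TRUE)
  s[fix] <- sub("e", ".0e", s[fix], fixed = TRUE)
  structure(s, class = "verbatim")
}

.poolToYaml <- function(p) {
  out <- list(f = p@f, t1 = p@t1, t2 = p@t2, k = p@k, dw = p@dw)
  if (is(p, "MTPool")) out$lineshape <- p@lineshape
  out
}

#' Serialize an exchange environment to yaml
#'
#' Inverse of [loadEnvironment()]; numeric fields are written with 15
#' significant digits so that save/load round trips are exact, and the key
#' order is canonical so that serialization is idempotent byte-for-byte.
#'
#' @param env a [CESTEnvironment-class].
#' @param file optional path; if `NULL` the yaml text is returned.
#' @return the yaml text (invisibly when written to `file`).
#' @export
saveEnvironment <- function(env, file = NULL) {
  stopifnot(is(env, "CESTEnvironment"))
  y <- list(water_pool = list(f = env@water@f, t1 = env@water@t1,
                              t2 = env@water@t2))
  if (length(env@cestPools)) {
    nms <- names(env@cestPools)
    if (is.null(nms)) nms <- paste0("pool_", seq_along(env@cestPools))
    y$cest_pool <- lapply(env@cestPools, .poolToYaml)
    names(y$cest_pool) <- nms
  }
  if (!is.null(env@mtPool)) y$mt_pool <- .poolToYaml(env@mtPool)
  y$b0 <- env@b0
  y$gamma <- env@gammaOver2pi
  y$rel_b1 <- env@relB1
  y$db0 <- env@db0
  for (nm in sort(names(env@extra))) y[[nm]] <- env@extra[[nm]]
  txt <- yaml::as.yaml(y, handlers = list(numeric = .verbatimNumber))
  if (!is.null(file)) {
    writeLines(sub("\n$", "", txt), file)
    return(invisible(txt))
  }
  txt
}
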