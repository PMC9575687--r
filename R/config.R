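#' @include AllClasses.R
NULL

.configDefaults <- function() list(
  seed = 1L,
  preset = "two_arm_v",
  atomsPerDomain = 12L,
  n = 1L,
  M = 20L,
  tau = 1L,
  snr = Inf,
  datatype = 1L,
  P = 64L,
  blobSigma = 1.5,
  nPDs = 1L,
  apertureDeg = 3,
  jitterOrientations = FALSE,
  method = "DM",
  preFilterSigma = 1.5,       # band limit before distances; 0 disables
  doubleFilter = NA,          # NA: automatic (on for data-types III/IV)
  d = 15L,
  r2Min = 0.7,
  nMax = 3L,
  constraint = NA_character_, # NA: parabola for I/II, general for III/IV
  thetaStep = 1,
  histBins = 40L,
  operatorMode = "cross",
  B = NA_integer_,            # NA: defaults to M in synthetic mode
  quantileLo = 0.02,          # robust arccos rescaling trim
  quantileHi = 0.98,
  senseMode = "ground_truth",
  kT = 1,
  voltageKV = 300,
  csMM = 2.7,
  amplitudeContrast = 0.1,
  pixelSizeA = 1.0,
  defocusMinUM = 0.5,
  defocusMaxUM = 2.5,
  occupancyMode = "uniform",
  weights = "",               # comma-separated per-state weights
  outDir = ""
)

## FNV-1a over the canonical text form (provenance stamp; no external deps)
.fnv1a <- function(txt) {
  bytes <- as.integer(charToRaw(txt))
  h <- 2166136261
  for (b in bytes) {
    ## xor only touches the low byte (b < 256); h may exceed 2^31
    h <- h - (h %% 256) + bitwXor(as.integer(h %% 256), b)
    ## 32-bit modular multiply by 16777619 using double split arithmetic
    lo <- (h %% 65536) * 16777619
    hi <- ((h %/% 65536) * 16777619) %% 65536
    h <- (lo + hi * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

.configText <- function(values) {
  keys <- sort(names(values))
  paste(vapply(keys, function(k) {
    v <- values[[k]]
    paste0(k, " = ", paste(format(v, digits = 17, trim = TRUE), collapse = ","))
  }, character(1)), collapse = "\n")
}

#' Build a run configuration
#'
#' All pipeline parameters in one flat, text-serializable object with
#' defaults; unknown keys are rejected. The provenance hash covers the
#' canonical text form, so two configs with equal parameters share a hash.
#'
#' @param ... named parameters overriding the defaults (see
#'   [writeRunConfig] for the full key list, which equals the defaults).
#' @return a [RunConfig-class].
#' @examples
#' cfg <- runConfig(n = 2, M = 20, tau = 5, datatype = 2, snr = 0.1)
#' @export
runConfig <- function(...) {
  over <- list(...)
  defaults <- .configDefaults()
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  values <- defaults
  for (k in names(over)) {
    tmpl <- defaults[[k]]
    v <- over[[k]]
    if (is.integer(tmpl)) v <- as.integer(v)
    else if (is.numeric(tmpl)) v <- as.numeric(v)
    else if (is.logical(tmpl)) v <- as.logical(v)
    else {
      v <- as.character(v)
      if (length(v) == 1 && identical(v, "NA")) v <- NA_character_
    }
    values[[k]] <- v
  }
  new("RunConfig", values = values, hash = .fnv1a(.configText(values)))
}

#' Write a run configuration as flat key=value text
#' @param config a [RunConfig-class].
#' @param path output path.
#' @export
writeRunConfig <- function(config, path) {
  txt <- .configText(config@values)
  writeLines(c(paste0("# manifoldCM run config (hash ", config@hash, ")"),
               txt), path)
  invisible(path)
}

#' Read a run configuration from flat key=value text
#'
#' Unknown keys are rejected; values are coerced to the default key types,
#' so a write/read round trip is lossless.
#'
#' @param path file path.
#' @return a [RunConfig-class].
#' @export
readRunConfig <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- regmatches(lines, regexec("^\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3)
  if (length(bad)) stop("malformed config line: ", lines[bad[1]])
  keys <- vapply(kv, `[`, character(1), 2)
  vals <- vapply(kv, `[`, character(1), 3)
  defaults <- .configDefaults()
  unknown <- setdiff(keys, names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  args <- list()
  for (q in seq_along(keys)) {
    tmpl <- defaults[[keys[q]]]
    raw <- trimws(vals[q])
    parts <- if (is.character(tmpl)) raw else strsplit(raw, ",")[[1]]
    args[[keys[q]]] <- if (is.character(tmpl)) parts else
      utils::type.convert(parts, as.is = TRUE)
  }
  do.call(runConfig, args)
}

#' @describeIn runConfig get one parameter value.
#' @param config a [RunConfig-class].
#' @param key parameter name.
#' @export
configValue <- function(config, key) {
  if (!key %in% names(config@values)) stop("unknown config key: ", key)
  config@values[[key]]
}
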