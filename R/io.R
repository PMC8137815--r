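#' @include AllClasses.R
NULL

#' Read a single-channel signal file
#'
#' Supports two plain-text dialects: one sample per line (the format of
#' the Bonn epileptology EEG segments, bare ASCII numbers) and CSV with a
#' named value column. The sampling frequency is resolved from, in order
#' of precedence, the `fs` argument and a JSON sidecar file
#' `<path>.json` with an `fs` entry; it is an error when neither is
#' available.
#'
#' @param path input file path.
#' @param fs sampling frequency in Hz; overrides any sidecar value.
#' @param format `"auto"` (by extension: `.csv` is CSV, anything else
#'   plain), `"plain"` or `"csv"`.
#' @param column name of the CSV value column (default `"value"`).
#' @return A [DigitalSignal-class].
#' @seealso [writeSignal()]
#' @export
readSignal <- function(path, fs = NULL, format = c("auto", "plain", "csv"),
                       column = "value") {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("signal file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "plain"
  if (format == "csv") {
    tab <- utils::read.csv(path)
    if (!column %in% names(tab))
      stop("column '", column, "' not found in ", path)
    x <- tab[[column]]
    if (!is.numeric(x))
      stop("column '", column, "' in ", path, " is not numeric")
  } else {
    txt <- readLines(path)
    txt <- txt[nzchar(trimws(txt))]
    x <- suppressWarnings(as.numeric(txt))
    if (anyNA(x))
      stop("unparseable sample at line ", which(is.na(x))[1], " of ", path)
  }
  if (is.null(fs)) fs <- readSidecarFs(path)
  if (is.null(fs))
    stop("sampling frequency not resolvable for ", path,
         ": pass fs or provide a '", basename(path), ".json' sidecar")
  digitalSignal(x, fs)
}

readSidecarFs <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) return(NULL)
  meta <- jsonlite::read_json(sidecar)
  if (is.null(meta$fs)) NULL else as.numeric(meta$fs)
}

#' Write a single-channel signal file
#'
#' Format-symmetric counterpart of [readSignal()]. Plain-text output has
#' one sample per line; CSV output has a header `index,value` with 0-based
#' indices. In both cases a JSON sidecar `<path>.json` records the
#' sampling frequency and sample count. Samples are written with 12
#' significant digits, so a write/read round trip is exact at that
#' precision.
#'
#' @param signal a [DigitalSignal-class].
#' @param path output file path.
#' @param format `"auto"`, `"plain"` or `"csv"` (as in [readSignal()]).
#' @return `path`, invisibly.
#' @export
writeSignal <- function(signal, path,
                        format = c("auto", "plain", "csv")) {
  stopifnot(is(signal, "DigitalSignal"))
  validObject(signal)
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "plain"
  vals <- sprintf("%.12g", samples(signal))
  if (format == "csv") {
    writeLines(c("index,value",
                 paste(seq_along(vals) - 1L, vals, sep = ",")), path)
  } else {
    writeLines(vals, path)
  }
  jsonlite::write_json(list(fs = samplingRate(signal),
                            n_samples = length(signal)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

pipelineSchema <- list(
  input = "path of the signal file to read",
  fs = "sampling frequency override in Hz",
  redundancy = "dictionary redundancy factor Q",
  iterations = "SALSA iteration count",
  mu = "augmented-Lagrangian penalty",
  lambda = "threshold weight",
  lambda_mode = "'relative-to-max' or 'absolute'",
  tolerance = "optional early-stopping tolerance",
  nominal_freq = "nominal interference frequency/frequencies in Hz",
  band_halfwidth = "powerline band half-width in Hz",
  line_threshold = "dominance threshold fraction",
  output = "list: denoised, compensation, spectrum, loss, report paths")

pipelineOutputKeys <- c("denoised", "compensation", "spectrum", "loss",
                        "report")

checkPipelineConfig <- function(config) {
  unknown <- setdiff(names(config), names(pipelineSchema))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(config$input))
    stop("config key 'input' is required")
  out <- config$output
  if (!is.null(out)) {
    unknown <- setdiff(names(out), pipelineOutputKeys)
    if (length(unknown))
      stop("unknown config key(s): ",
           paste(paste0("output.", unknown), collapse = ", "))
  }
  invisible(config)
}

#' Run the full interference-removal pipeline from a configuration
#'
#' Reads a signal, runs [removePli()], and writes the requested artifacts:
#' denoised signal, compensation signal, sparse-spectrum CSV, loss-history
#' CSV and a JSON run report (settings echo, dominant and selected lines,
#' estimated harmonic parameters of the compensation, residual energy
#' ratio). The run is deterministic: identical config and input give
#' byte-identical outputs.
#'
#' @param config either a named list or the path of a YAML or JSON config
#'   file. Recognized keys: `input`, `fs`, `redundancy`, `iterations`,
#'   `mu`, `lambda`, `lambda_mode`, `tolerance`, `nominal_freq`,
#'   `band_halfwidth`, `line_threshold`, and `output` with sub-keys
#'   `denoised`, `compensation`, `spectrum`, `loss`, `report`. Unknown
#'   keys are rejected.
#' @return The [DetectionResult-class], invisibly.
#' @export
runPipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE))
      yaml::read_yaml(config)
    else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a named list or a file path")
  checkPipelineConfig(config)

  signal <- readSignal(config$input, fs = config$fs)
  settings <- solverSettings(
    lambda = config$lambda %||% 2 / 3,
    mu = config$mu %||% 1,
    maxIter = config$iterations %||% 100L,
    relTol = config$tolerance %||% NA_real_,
    lambdaMode = config$lambda_mode %||% "relative-to-max")
  result <- removePli(signal,
                      redundancy = config$redundancy %||% 10,
                      settings = settings,
                      nominalFreq = config$nominal_freq %||% 50,
                      halfWidth = config$band_halfwidth %||% 2,
                      thresholdFrac = config$line_threshold %||% 0.01)

  out <- config$output
  if (!is.null(out$denoised)) writeSignal(denoised(result), out$denoised)
  if (!is.null(out$compensation))
    writeSignal(compensation(result), out$compensation)
  if (!is.null(out$spectrum)) writeSpectrum(result@coefficients, out$spectrum)
  if (!is.null(out$loss)) writeLossHistory(lossHistory(result), out$loss)
  if (!is.null(out$report)) writeRunReport(result, settings, config,
                                           out$report)
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

writeRunReport <- function(result, settings, config, path) {
  comp <- compensation(result)
  est <- if (any(samples(comp) != 0)) {
    hp <- estimateHarmonicParams(comp)
    list(amplitude = hp@amplitude, frequency_hz = hp@frequency,
         phase_rad = hp@phase)
  } else NULL
  linesAsList <- function(df) {
    if (!nrow(df)) return(list())
    lapply(seq_len(nrow(df)), function(i)
      list(bin = df$bin[i], frequency_hz = df$frequency[i],
           one_sided_amplitude = df$amplitude[i]))
  }
  report <- list(
    settings = list(
      lambda = settings@lambdaWeight, lambda_mode = settings@lambdaMode,
      mu = settings@mu, iterations = settings@maxIter,
      tolerance = if (is.na(settings@relTol)) NULL else settings@relTol,
      redundancy = config$redundancy %||% 10,
      nominal_freq = config$nominal_freq %||% 50,
      band_halfwidth = config$band_halfwidth %||% 2,
      line_threshold = config$line_threshold %||% 0.01),
    n_samples = length(result@input),
    fs = samplingRate(result@input),
    dominant_lines = linesAsList(dominantLines(result)),
    pli_lines = linesAsList(pliLines(result)),
    estimated_harmonic = est,
    residual_energy_ratio =
      sqrt(sum(samples(denoised(result))^2) /
             max(sum(samples(result@input)^2), .Machine$double.xmin)),
    final_loss = utils::tail(lossHistory(result), 1))
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
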