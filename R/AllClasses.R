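#' @include AllGenerics.R
NULL

#' DigitalSignal: a uniformly sampled real-valued signal
#'
#' Container for a single-channel digitized signal: a finite sequence of
#' real samples together with its sampling frequency. Sample `n` (0-based)
#' is taken at time `t_n = n / fs`.
#'
#' @slot samples numeric vector of finite sample values, length N >= 1.
#' @slot fs sampling frequency in Hz, strictly positive.
#'
#' @seealso [digitalSignal()], [generatePli()], [readSignal()]
#' @export
setClass("DigitalSignal",
         slots = c(samples = "numeric", fs = "numeric"))

setValidity("DigitalSignal", function(object) {
  msg <- character()
  if (length(object@samples) < 1L)
    msg <- c(msg, "signal must contain at least one sample")
  if (length(object@samples) && !all(is.finite(object@samples)))
    msg <- c(msg, "all samples must be finite")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive finite number")
  if (length(msg)) msg else TRUE
})

#' Construct a DigitalSignal
#'
#' @param samples numeric vector of sample values.
#' @param fs sampling frequency in Hz.
#' @return A [DigitalSignal-class] object.
#' @examples
#' digitalSignal(sin(2 * pi * 5 * (0:99) / 100), fs = 100)
#' @export
digitalSignal <- function(samples, fs) {
  new("DigitalSignal", samples = as.numeric(samples), fs = as.numeric(fs))
}

#' RedundantFourierDictionary: a K-atom tight Fourier frame
#'
#' Implicit representation of the N x K dictionary whose k-th atom is the
#' sampled complex exponential `exp(2i*pi*k*n/K)`, `n = 0..N-1`. Atom k has
#' physical frequency `k * fs / K`; the grid spacing is `fs / K`, a factor
#' Q = K/N finer than the orthonormal FFT grid. The atoms form a tight
#' frame: `A A^H = p I` with frame constant `p = K`, so analysis followed
#' by synthesis is exact up to the scalar p. Synthesis and analysis are
#' never materialized as a matrix; both run through length-K FFTs.
#'
#' @slot nSamples signal length N.
#' @slot nAtoms number of atoms K = M*N with integer M >= 2.
#' @slot fs sampling frequency in Hz.
#'
#' @seealso [buildDictionary()], [dictApply()], [dictAdjoint()]
#' @export
setClass("RedundantFourierDictionary",
         slots = c(nSamples = "integer", nAtoms = "integer", fs = "numeric"))

setValidity("RedundantFourierDictionary", function(object) {
  msg <- character()
  N <- object@nSamples; K <- object@nAtoms
  if (length(N) != 1L || is.na(N) || N < 1L)
    msg <- c(msg, "nSamples must be a positive integer")
  if (length(K) != 1L || is.na(K) || K < 2L)
    msg <- c(msg, "nAtoms must be an integer >= 2")
  if (!length(msg) && (K %% N != 0L || K %/% N < 2L))
    msg <- c(msg, "nAtoms must be an integer multiple M*nSamples with M >= 2")
  if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
    msg <- c(msg, "fs must be a single positive finite number")
  if (length(msg)) msg else TRUE
})

#' SparseCoefficients: dictionary-domain representation of a signal
#'
#' A length-K complex coefficient vector tied to the
#' [RedundantFourierDictionary-class] it was computed against. Coefficients
#' live on the synthesis scale (`y = A x` with unit-magnitude atoms), so a
#' real cosine of amplitude a contributes about a/2 to each member of its
#' conjugate pair; the [oneSidedAmplitude()] view folds the pair into one
#' physical amplitude.
#'
#' @slot values complex vector of length K.
#' @slot dict the source dictionary.
#'
#' @export
setClass("SparseCoefficients",
         slots = c(values = "complex", dict = "RedundantFourierDictionary"))

setValidity("SparseCoefficients", function(object) {
  if (length(object@values) != object@dict@nAtoms)
    "length of values must equal the number of dictionary atoms" else TRUE
})

#' Construct a SparseCoefficients object
#'
#' @param values complex vector of length `nAtoms(dict)`.
#' @param dict a [RedundantFourierDictionary-class].
#' @return A [SparseCoefficients-class] object.
#' @export
sparseCoefficients <- function(values, dict) {
  new("SparseCoefficients", values = as.complex(values), dict = dict)
}

#' SolverSettings: parameters of the SALSA iteration
#'
#' @slot lambdaWeight nonnegative threshold weight lambda; a scalar or a
#'   length-K vector. In `"relative-to-max"` mode it is a dimensionless
#'   fraction of the largest back-projected coefficient magnitude
#'   `max|A^H y| / p`; in `"absolute"` mode it is used as is.
#' @slot mu positive augmented-Lagrangian penalty parameter.
#' @slot maxIter number of iterations to run (>= 1).
#' @slot relTol optional early-stopping tolerance on the relative change of
#'   the loss; `NA_real_` (the default) disables early stopping so that
#'   fixed iteration counts are reproduced exactly.
#' @slot lambdaMode `"relative-to-max"` or `"absolute"`.
#'
#' @seealso [solverSettings()], [salsaBpdn()]
#' @export
setClass("SolverSettings",
         slots = c(lambdaWeight = "numeric", mu = "numeric",
                   maxIter = "integer", relTol = "numeric",
                   lambdaMode = "character"))

setValidity("SolverSettings", function(object) {
  msg <- character()
  if (!length(object@lambdaWeight) || any(!is.finite(object@lambdaWeight)) ||
      any(object@lambdaWeight < 0))
    msg <- c(msg, "lambdaWeight must be nonnegative and finite")
  if (length(object@mu) != 1L || !is.finite(object@mu) || object@mu <= 0)
    msg <- c(msg, "mu must be a single positive number")
  if (length(object@maxIter) != 1L || is.na(object@maxIter) ||
      object@maxIter < 1L)
    msg <- c(msg, "maxIter must be an integer >= 1")
  if (length(object@relTol) != 1L ||
      (!is.na(object@relTol) && object@relTol <= 0))
    msg <- c(msg, "relTol must be NA or a single positive number")
  if (length(object@lambdaMode) != 1L ||
      !object@lambdaMode %in% c("relative-to-max", "absolute"))
    msg <- c(msg, "lambdaMode must be 'relative-to-max' or 'absolute'")
  if (length(msg)) msg else TRUE
})

#' Construct solver settings
#'
#' Defaults reproduce the documented off-grid simulation: `mu = 1` and a
#' relative threshold weight of 2/3, i.e. an effective soft-threshold
#' `lambda/mu` equal to two-thirds of the largest back-projected coefficient
#' magnitude of the input. See the methods vignette for how these were
#' chosen.
#'
#' @param lambda threshold weight (scalar or length-K vector); interpreted
#'   according to `lambdaMode`.
#' @param mu augmented-Lagrangian penalty parameter, positive.
#' @param maxIter iteration count.
#' @param relTol optional early-stopping tolerance (default `NA`: off).
#' @param lambdaMode `"relative-to-max"` (default) or `"absolute"`.
#' @return A [SolverSettings-class] object.
#' @examples
#' solverSettings()                      # package defaults
#' solverSettings(lambda = 0.05, maxIter = 1000)
#' @export
solverSettings <- function(lambda = 2 / 3, mu = 1, maxIter = 100L,
                           relTol = NA_real_,
                           lambdaMode = c("relative-to-max", "absolute")) {
  new("SolverSettings",
      lambdaWeight = as.numeric(lambda), mu = as.numeric(mu),
      maxIter = as.integer(maxIter), relTol = as.numeric(relTol),
      lambdaMode = match.arg(lambdaMode))
}

#' SalsaState: the evolving variables of one SALSA run
#'
#' @slot x complex length-K primal coefficient vector.
#' @slot d complex length-K scaled dual (Lagrange multiplier) vector.
#' @slot iter iterations completed so far.
#' @export
setClass("SalsaState",
         slots = c(x = "complex", d = "complex", iter = "integer"))

#' DetectionResult: outcome of one interference-removal run
#'
#' Holds the input, the synthesized compensation waveform, the denoised
#' signal (`input - compensation`, elementwise and exact), the dominant and
#' powerline-band spectral lines, the full sparse coefficient vector and
#' the solver loss history.
#'
#' @slot input the analysed [DigitalSignal-class].
#' @slot denoised input minus compensation.
#' @slot compensation reconstructed interference waveform.
#' @slot dominantLines data.frame of all dominant spectral lines.
#' @slot pliLines data.frame of the lines inside the powerline band(s).
#' @slot coefficients the full [SparseCoefficients-class].
#' @slot lossHistory numeric per-iteration loss values.
#'
#' @seealso [removePli()]
#' @export
setClass("DetectionResult",
         slots = c(input = "DigitalSignal",
                   denoised = "DigitalSignal",
                   compensation = "DigitalSignal",
                   dominantLines = "data.frame",
                   pliLines = "data.frame",
                   coefficients = "SparseCoefficients",
                   lossHistory = "numeric"))

setValidity("DetectionResult", function(object) {
  msg <- character()
  n <- length(object@input@samples)
  if (length(object@denoised@samples) != n ||
      length(object@compensation@samples) != n)
    msg <- c(msg, "input, denoised and compensation must share one length")
  fs <- object@input@fs
  if (object@denoised@fs != fs || object@compensation@fs != fs)
    msg <- c(msg, "input, denoised and compensation must share one fs")
  if (!identical(object@denoised@samples,
                 object@input@samples - object@compensation@samples))
    msg <- c(msg, "denoised must equal input - compensation exactly")
  if (length(msg)) msg else TRUE
})

#' HarmonicParams: amplitude, frequency and phase of one sinusoid
#'
#' Parameters of a simple harmonic wave
#' `amplitude * cos(2*pi*frequency*t + phase)`. The phase is canonicalized
#' to `[-pi, pi)`.
#'
#' @slot amplitude nonnegative amplitude (arbitrary units).
#' @slot frequency nonnegative frequency in Hz.
#' @slot phase initial phase in radians, in `[-pi, pi)`.
#'
#' @seealso [harmonicParams()], [generatePli()], [estimateHarmonicParams()]
#' @export
setClass("HarmonicParams",
         slots = c(amplitude = "numeric", frequency = "numeric",
                   phase = "numeric"))

setValidity("HarmonicParams", function(object) {
  msg <- character()
  if (length(object@amplitude) != 1L || !is.finite(object@amplitude) ||
      object@amplitude < 0)
    msg <- c(msg, "amplitude must be a single nonnegative number")
  if (length(object@frequency) != 1L || !is.finite(object@frequency) ||
      object@frequency < 0)
    msg <- c(msg, "frequency must be a single nonnegative number")
  if (length(object@phase) != 1L || !is.finite(object@phase) ||
      object@phase < -pi || object@phase >= pi)
    msg <- c(msg, "phase must be a single number in [-pi, pi)")
  if (length(msg)) msg else TRUE
})

## ---- accessors -----------------------------------------------------------

#' @rdname samples
#' @export
setMethod("samples", "DigitalSignal", function(object) object@samples)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "DigitalSignal", function(object) object@fs)

#' @rdname samplingRate
#' @export
setMethod("samplingRate", "RedundantFourierDictionary",
          function(object) object@fs)

#' @rdname nSamples
#' @export
setMethod("nSamples", "DigitalSignal",
          function(object) length(object@samples))

#' @rdname nSamples
#' @export
setMethod("nSamples", "RedundantFourierDictionary",
          function(object) object@nSamples)

#' Length of a DigitalSignal (number of samples)
#'
#' @param x a [DigitalSignal-class].
#' @return Integer sample count.
#' @export
setMethod("length", "DigitalSignal", function(x) length(x@samples))

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "RedundantFourierDictionary",
          function(object) object@nAtoms)

#' @rdname nAtoms
#' @export
setMethod("nAtoms", "SparseCoefficients",
          function(object) object@dict@nAtoms)

#' @rdname redundancy
#' @export
setMethod("redundancy", "RedundantFourierDictionary",
          function(object) object@nAtoms %/% object@nSamples)

#' @rdname frameConstant
#' @export
setMethod("frameConstant", "RedundantFourierDictionary",
          function(object) as.numeric(object@nAtoms))

#' @rdname frequencyGrid
#' @export
setMethod("frequencyGrid", "RedundantFourierDictionary", function(object) {
  K <- object@nAtoms
  (seq_len(K) - 1) * object@fs / K
})

#' @rdname frequencyGrid
#' @export
setMethod("frequencyGrid", "SparseCoefficients",
          function(object) frequencyGrid(object@dict))

#' @rdname coefValues
#' @export
setMethod("coefValues", "SparseCoefficients", function(object) object@values)

#' @rdname dictionary
#' @export
setMethod("dictionary", "SparseCoefficients", function(object) object@dict)

#' Length of a SparseCoefficients vector (number of atoms)
#'
#' @param x a [SparseCoefficients-class].
#' @return Integer atom count K.
#' @export
setMethod("length", "SparseCoefficients", function(x) length(x@values))

#' @rdname denoised
#' @export
setMethod("denoised", "DetectionResult", function(object) object@denoised)

#' @rdname compensation
#' @export
setMethod("compensation", "DetectionResult",
          function(object) object@compensation)

#' @rdname dominantLines
#' @export
setMethod("dominantLines", "DetectionResult",
          function(object) object@dominantLines)

#' @rdname pliLines
#' @export
setMethod("pliLines", "DetectionResult", function(object) object@pliLines)

#' @rdname lossHistory
#' @export
setMethod("lossHistory", "DetectionResult",
          function(object) object@lossHistory)

## ---- show methods --------------------------------------------------------

setMethod("show", "DigitalSignal", function(object) {
  n <- length(object@samples)
  cat("DigitalSignal:", n, "samples at", object@fs, "Hz",
      sprintf("(%.4g s)\n", n / object@fs))
  cat("  range [", format(min(object@samples), digits = 4), ", ",
      format(max(object@samples), digits = 4), "]\n", sep = "")
})

setMethod("show", "RedundantFourierDictionary", function(object) {
  cat("RedundantFourierDictionary: K =", object@nAtoms, "atoms for N =",
      object@nSamples, "samples (Q =", redundancy(object), ")\n")
  cat("  grid step", format(spectralResolution(object), digits = 6),
      "Hz, frame constant p =", frameConstant(object), "\n")
})

setMethod("show", "SparseCoefficients", function(object) {
  a <- oneSidedAmplitude(object)
  cat("SparseCoefficients: K =", length(object@values), "over dictionary",
      "grid step", format(spectralResolution(object@dict), digits = 6),
      "Hz\n")
  k <- which.max(a)
  cat("  largest one-sided amplitude", format(a[k], digits = 4), "at",
      format((k - 1) * object@dict@fs / object@dict@nAtoms, digits = 6),
      "Hz\n")
})

setMethod("show", "SolverSettings", function(object) {
  cat("SolverSettings: lambda =",
      paste(format(object@lambdaWeight, digits = 4), collapse = ","),
      paste0("(", object@lambdaMode, ")"),
      "mu =", object@mu, "maxIter =", object@maxIter,
      "relTol =", object@relTol, "\n")
})

setMethod("show", "DetectionResult", function(object) {
  cat("DetectionResult on", length(object@input@samples), "samples at",
      object@input@fs, "Hz\n")
  cat("  dominant lines:", nrow(object@dominantLines),
      " in powerline band:", nrow(object@pliLines), "\n")
  if (nrow(object@pliLines))
    cat("  removed lines at",
        paste(format(object@pliLines$frequency, digits = 6),
              collapse = ", "), "Hz\n")
  rr <- sqrt(sum(object@compensation@samples^2) /
               max(sum(object@input@samples^2), .Machine$double.xmin))
  cat("  compensation / input energy ratio:",
      format(rr, digits = 4), "\n")
})

setMethod("show", "HarmonicParams", function(object) {
  cat(sprintf("HarmonicParams: amplitude %.6g, frequency %.6g Hz, phase %.6g rad\n",
              object@amplitude, object@frequency, object@phase))
})
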