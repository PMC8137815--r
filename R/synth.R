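#' @include AllClasses.R
NULL

#' Describe one harmonic component
#'
#' Convenience constructor for [HarmonicParams-class]. The phase is
#' canonicalized into `[-pi, pi)`.
#'
#' @param amplitude nonnegative amplitude (arbitrary units).
#' @param frequency nonnegative frequency in Hz.
#' @param phase initial phase in radians (any value; wrapped).
#' @return A [HarmonicParams-class] object.
#' @examples
#' harmonicParams(1, 50.15, pi / 3)
#' @export
harmonicParams <- function(amplitude, frequency, phase = 0) {
  new("HarmonicParams",
      amplitude = as.numeric(amplitude),
      frequency = as.numeric(frequency),
      phase = canonicalPhase(as.numeric(phase)))
}

## wrap into [-pi, pi); already-canonical values pass through untouched
canonicalPhase <- function(phase) {
  if (phase >= -pi && phase < pi) phase
  else ((phase + pi) %% (2 * pi)) - pi
}

#' Generate a pure powerline-interference cosine
#'
#' Samples `amplitude * cos(2*pi*frequency*n/fs + phase)` for
#' `n = 0..nSamples-1`. This is the model of mains interference used
#' throughout the package: a single harmonic of (possibly off-grid)
#' frequency near 50 or 60 Hz.
#'
#' @param params a [HarmonicParams-class] (see [harmonicParams()]).
#' @param nSamples number of samples, >= 1.
#' @param fs sampling frequency in Hz, > 0.
#' @return A [DigitalSignal-class].
#' @examples
#' ## 1 s of a 50.15 Hz unit cosine with phase pi/3, sampled at 1 kHz
#' pli <- generatePli(harmonicParams(1, 50.15, pi / 3), 1000, 1000)
#' samples(pli)[1]   # cos(pi/3) = 0.5
#' @export
generatePli <- function(params, nSamples, fs) {
  stopifnot(is(params, "HarmonicParams"))
  validObject(params)
  if (length(nSamples) != 1L || !is.finite(nSamples) || nSamples < 1)
    stop("nSamples must be a positive integer")
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  n <- seq_len(nSamples) - 1
  digitalSignal(params@amplitude *
                  cos(2 * pi * params@frequency * n / fs + params@phase), fs)
}

#' Generate a harmonic mixture with optional Gaussian background
#'
#' Sums an arbitrary list of harmonic components and adds seeded white
#' Gaussian background of a given standard deviation. The Gaussian
#' surrogate stands in for the broadband brain activity on which mains
#' interference rides; it is reproducible bit-for-bit for a fixed seed and
#' never touches the caller's RNG state.
#'
#' @param components list of [HarmonicParams-class] objects (may be empty).
#' @param backgroundSd standard deviation of the Gaussian background, >= 0.
#' @param seed integer seed; required whenever `backgroundSd > 0`.
#' @param nSamples number of samples.
#' @param fs sampling frequency in Hz.
#' @return A [DigitalSignal-class].
#' @examples
#' sig <- generateMixture(
#'   list(harmonicParams(1, 10), harmonicParams(0.5, 50)),
#'   backgroundSd = 0.1, seed = 1, nSamples = 1000, fs = 1000)
#' @export
generateMixture <- function(components = list(), backgroundSd = 0, seed = NULL,
                            nSamples, fs) {
  if (length(backgroundSd) != 1L || !is.finite(backgroundSd) ||
      backgroundSd < 0)
    stop("backgroundSd must be a single nonnegative number")
  if (length(nSamples) != 1L || !is.finite(nSamples) || nSamples < 1)
    stop("nSamples must be a positive integer")
  if (length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  x <- numeric(nSamples)
  for (cmp in components) {
    stopifnot(is(cmp, "HarmonicParams"))
    x <- x + samples(generatePli(cmp, nSamples, fs))
  }
  if (backgroundSd > 0) {
    if (is.null(seed))
      stop("a seed is required when backgroundSd > 0")
    x <- x + localRnorm(seed, nSamples, backgroundSd)
  }
  digitalSignal(x, fs)
}

## seeded normal draws that leave the global RNG state untouched
localRnorm <- function(seed, n, sd) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  stats::rnorm(n, mean = 0, sd = sd)
}
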