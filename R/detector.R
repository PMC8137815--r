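#' @include AllClasses.R
NULL

#' Find dominant spectral lines of a sparse spectrum
#'
#' Selects the positive-frequency bins (`k = 0..K/2`) whose one-sided
#' amplitude reaches `thresholdFrac` times the maximum one-sided amplitude,
#' sorted by descending amplitude with ties broken by ascending frequency.
#' Each returned line implicitly stands for itself plus its conjugate
#' partner at bin K-k.
#'
#' @param coeffs a [SparseCoefficients-class].
#' @param thresholdFrac fraction of the maximum amplitude, in (0, 1].
#' @return data.frame with columns `bin` (0-based), `frequency` (Hz),
#'   `coefficient` (complex) and `amplitude` (one-sided); zero rows when
#'   all coefficients vanish.
#' @export
findDominantLines <- function(coeffs, thresholdFrac = 0.01) {
  stopifnot(is(coeffs, "SparseCoefficients"))
  if (length(thresholdFrac) != 1L || !is.finite(thresholdFrac) ||
      thresholdFrac <= 0 || thresholdFrac > 1)
    stop("thresholdFrac must be a single number in (0, 1]")
  a <- oneSidedAmplitude(coeffs)
  K <- length(coeffs@values)
  fs <- coeffs@dict@fs
  amax <- max(a)
  if (amax == 0) return(emptyLines())
  keep <- which(a >= thresholdFrac * amax)
  lines <- data.frame(bin = keep - 1L,
                      frequency = (keep - 1) * fs / K,
                      coefficient = coeffs@values[keep],
                      amplitude = a[keep])
  lines[order(-lines$amplitude, lines$frequency), , drop = FALSE]
}

emptyLines <- function() {
  data.frame(bin = integer(), frequency = numeric(),
             coefficient = complex(), amplitude = numeric())
}

#' Restrict spectral lines to a powerline band
#'
#' Keeps the lines whose frequency lies within `halfWidth` Hz of any of
#' the nominal frequencies (inclusive on both ends), preserving the input
#' order. Mains frequency drifts by up to about +-2 Hz in real power
#' systems, hence the default band of 50 +- 2 Hz.
#'
#' @param lines data.frame as returned by [findDominantLines()].
#' @param nominalFreq nominal interference frequency (Hz); may be a vector
#'   to mask several disjoint bands (e.g. `c(50, 76)`).
#' @param halfWidth half-width of each band in Hz, >= 0.
#' @return The matching subset of `lines`, order preserved.
#' @export
selectPliLines <- function(lines, nominalFreq = 50, halfWidth = 2) {
  if (any(nominalFreq <= 0)) stop("nominalFreq must be positive")
  if (length(halfWidth) != 1L || !is.finite(halfWidth) || halfWidth < 0)
    stop("halfWidth must be a single nonnegative number")
  if (nrow(lines) == 0L) return(lines)
  inBand <- Reduce(`|`, lapply(nominalFreq, function(f0)
    abs(lines$frequency - f0) <= halfWidth))
  lines[inBand, , drop = FALSE]
}

#' Synthesize a waveform from selected spectral lines
#'
#' Places the selected coefficients (and, for interior bins, their implied
#' conjugate partners at K-k) into an otherwise zero length-K vector and
#' takes the real part of the dictionary synthesis. All other spectral
#' content is zero, so the result contains exactly the selected
#' narrow-band components.
#'
#' @param lines data.frame with columns `bin` and `coefficient` (as
#'   produced by [findDominantLines()] / [selectPliLines()]).
#' @param dict the [RedundantFourierDictionary-class] the bins refer to.
#' @return A [DigitalSignal-class] of length N.
#' @export
reconstructComponent <- function(lines, dict) {
  K <- nAtoms(dict)
  z <- complex(K)
  if (nrow(lines)) {
    k <- lines$bin
    if (any(k != round(k)) || any(k < 0) || any(k > K %/% 2))
      stop("line bin index out of range [0, K/2]")
    z[k + 1L] <- lines$coefficient
    interior <- k > 0 & k < K / 2
    z[K - k[interior] + 1L] <- Conj(lines$coefficient[interior])
  }
  digitalSignal(Re(dictApply(dict, z)), samplingRate(dict))
}

#' Detect and remove powerline interference from a signal
#'
#' End-to-end pipeline: sparse-code the signal over a redundant Fourier
#' dictionary with [salsaBpdn()], find the dominant spectral lines, keep
#' those inside the powerline band(s), synthesize the compensation
#' waveform from them and subtract it. When no dominant line falls inside
#' the band a warning is signaled and the signal is returned unchanged
#' (zero compensation).
#'
#' @param signal a [DigitalSignal-class].
#' @param redundancy integer dictionary redundancy factor Q = K/N
#'   (default 10).
#' @param settings a [SolverSettings-class]; see [solverSettings()].
#' @param nominalFreq nominal interference frequency (Hz); vector allowed
#'   for several bands. Default 50 (use 60 for 60 Hz mains).
#' @param halfWidth band half-width in Hz (default 2).
#' @param thresholdFrac dominance threshold as a fraction of the maximum
#'   one-sided amplitude (default 0.01).
#' @return A [DetectionResult-class]. The invariant
#'   `samples(input) == samples(denoised) + samples(compensation)` holds
#'   exactly.
#' @examples
#' pli <- generatePli(harmonicParams(0.5, 50.15, pi / 3), 1000, 1000)
#' eeg <- generateMixture(list(harmonicParams(1, 10)), nSamples = 1000,
#'                        fs = 1000)
#' corrupted <- digitalSignal(samples(eeg) + samples(pli), 1000)
#' res <- removePli(corrupted)
#' res
#' @export
removePli <- function(signal, redundancy = 10,
                      settings = solverSettings(),
                      nominalFreq = 50, halfWidth = 2,
                      thresholdFrac = 0.01) {
  stopifnot(is(signal, "DigitalSignal"))
  validObject(signal)
  dict <- buildDictionary(length(signal), redundancy, samplingRate(signal))
  fit <- salsaBpdn(signal, dict, settings)
  dominant <- findDominantLines(fit$coefficients, thresholdFrac)
  pli <- selectPliLines(dominant, nominalFreq, halfWidth)
  if (nrow(pli) == 0L) {
    warning("no dominant spectral line inside the powerline band; ",
            "signal returned unchanged")
    comp <- digitalSignal(numeric(length(signal)), samplingRate(signal))
  } else {
    comp <- reconstructComponent(pli, dict)
  }
  new("DetectionResult",
      input = signal,
      denoised = digitalSignal(samples(signal) - samples(comp),
                               samplingRate(signal)),
      compensation = comp,
      dominantLines = dominant,
      pliLines = pli,
      coefficients = fit$coefficients,
      lossHistory = fit$lossHistory)
}

#' Estimate amplitude, frequency and phase of a sinusoidal component
#'
#' Locates the strongest sinusoid of a (near-)harmonic waveform from the
#' peak of a finely zero-padded FFT (grid `fs/(16N)`), then sharpens the
#' frequency by minimizing the least-squares residual of a single
#' cosine/sine pair within one fine-grid step of the peak, and reads
#' amplitude and phase from that fit. The residual refinement is exact for
#' a pure sinusoid, where reading `|X(f)|` at its maximum would be biased
#' by the negative-frequency image. Intended for narrow-band components
#' such as a reconstructed interference waveform.
#'
#' @param component a [DigitalSignal-class]; must not be identically zero.
#' @return A [HarmonicParams-class].
#' @examples
#' sig <- generatePli(harmonicParams(2, 50, 0), 1000, 1000)
#' estimateHarmonicParams(sig)  # recovers (2, 50, 0)
#' @export
estimateHarmonicParams <- function(component) {
  stopifnot(is(component, "DigitalSignal"))
  x <- samples(component)
  if (all(x == 0))
    stop("harmonic parameters are undefined for an all-zero component")
  N <- length(x)
  fs <- samplingRate(component)
  pad <- 16L * N
  X <- stats::fft(c(x, numeric(pad - N)))
  half <- pad %/% 2
  kPeak <- which.max(Mod(X[seq_len(half + 1)])) - 1L
  step <- fs / pad
  fGuess <- kPeak * step
  t <- (0:(N - 1)) / fs
  rssAt <- function(f) {
    sum(stats::lm.fit(cbind(cos(2 * pi * f * t), sin(2 * pi * f * t)),
                      x)$residuals^2)
  }
  lo <- max(fGuess - step, step / 16)
  hi <- min(fGuess + step, fs / 2)
  f <- if (hi > lo) stats::optimize(rssAt, c(lo, hi), tol = 1e-10)$minimum
       else fGuess
  co <- stats::lm.fit(cbind(cos(2 * pi * f * t), sin(2 * pi * f * t)),
                      x)$coefficients
  harmonicParams(amplitude = sqrt(sum(co^2)),
                 frequency = f,
                 phase = atan2(-co[2], co[1]))
}
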