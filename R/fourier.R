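#' @include AllClasses.R
NULL

#' Orthonormal FFT spectrum of a signal
#'
#' Coefficients of the 1/sqrt(N)-normalized discrete Fourier basis, i.e.
#' `c_k = (1/sqrt(N)) * sum_n x_n exp(-2i*pi*k*n/N)`. Under this
#' normalization the transform is unitary: the l2 norm of the coefficients
#' equals the l2 norm of the samples (Parseval), and
#' [inverseFftSpectrum()] reconstructs the signal to machine precision.
#'
#' @param signal a [DigitalSignal-class].
#' @return Complex vector of length N; element k+1 belongs to frequency
#'   `k * fs / N`.
#' @seealso [fourierCoefficientAt()] for off-grid frequencies.
#' @export
fftSpectrum <- function(signal) {
  stopifnot(is(signal, "DigitalSignal"))
  x <- samples(signal)
  stats::fft(x) / sqrt(length(x))
}

#' Inverse of the orthonormal FFT spectrum
#'
#' @param coeffs complex vector as returned by [fftSpectrum()].
#' @return Complex vector of time-domain samples; take `Re()` for a real
#'   signal.
#' @export
inverseFftSpectrum <- function(coeffs) {
  stats::fft(coeffs, inverse = TRUE) / sqrt(length(coeffs))
}

#' Fourier coefficient at an arbitrary frequency
#'
#' Evaluates `X(f) = sum_{n=0}^{N-1} x_n exp(-2i*pi*f*n/fs)` directly, with
#' no normalization. On a grid frequency `k*fs/N` this equals `sqrt(N)`
#' times the orthonormal [fftSpectrum()] coefficient at bin k. Frequencies
#' outside `[0, fs/2]` are permitted but alias.
#'
#' @param signal a [DigitalSignal-class].
#' @param freq frequency (or vector of frequencies) in Hz.
#' @return Complex scalar (or vector matching `freq`).
#' @export
fourierCoefficientAt <- function(signal, freq) {
  stopifnot(is(signal, "DigitalSignal"))
  x <- samples(signal)
  n <- seq_along(x) - 1
  fs <- samplingRate(signal)
  vapply(freq,
         function(f) sum(x * exp(-2i * pi * f * n / fs)),
         complex(1))
}

#' Build a redundant Fourier tight-frame dictionary
#'
#' Creates the implicit N x K dictionary with `K = redundancy * nSamples`
#' equally spaced sinusoidal atoms. The redundancy factor must be an
#' integer of at least 2, so that the frequency grid `fs/K` refines the FFT
#' grid `fs/N` by a whole factor.
#'
#' @param nSamples signal length N.
#' @param redundancy integer redundancy factor M = K/N, >= 2.
#' @param fs sampling frequency in Hz.
#' @return A [RedundantFourierDictionary-class].
#' @examples
#' buildDictionary(1000, 10, 1000)  # K = 10000 atoms, 0.1 Hz grid
#' @export
buildDictionary <- function(nSamples, redundancy, fs) {
  if (length(redundancy) != 1L || !is.finite(redundancy) ||
      redundancy != round(redundancy) || redundancy < 2)
    stop("redundancy must be an integer >= 2")
  if (length(nSamples) != 1L || !is.finite(nSamples) || nSamples < 1 ||
      nSamples != round(nSamples))
    stop("nSamples must be a positive integer")
  new("RedundantFourierDictionary",
      nSamples = as.integer(nSamples),
      nAtoms = as.integer(redundancy) * as.integer(nSamples),
      fs = as.numeric(fs))
}

#' @rdname dictApply
#' @export
setMethod("dictApply",
          signature(dict = "RedundantFourierDictionary", coeffs = "complex"),
          function(dict, coeffs) {
  if (length(coeffs) != dict@nAtoms)
    stop("coefficient vector length must equal the number of atoms K")
  stats::fft(coeffs, inverse = TRUE)[seq_len(dict@nSamples)]
})

#' @rdname dictApply
#' @export
setMethod("dictApply",
          signature(dict = "RedundantFourierDictionary", coeffs = "numeric"),
          function(dict, coeffs) {
  dictApply(dict, as.complex(coeffs))
})

#' @rdname dictApply
#' @export
setMethod("dictApply",
          signature(dict = "RedundantFourierDictionary",
                    coeffs = "SparseCoefficients"),
          function(dict, coeffs) {
  dictApply(dict, coefValues(coeffs))
})

#' @rdname dictAdjoint
#' @export
setMethod("dictAdjoint",
          signature(dict = "RedundantFourierDictionary", signal = "complex"),
          function(dict, signal) {
  if (length(signal) != dict@nSamples)
    stop("signal length must equal the dictionary's nSamples N")
  stats::fft(c(signal, complex(dict@nAtoms - dict@nSamples)))
})

#' @rdname dictAdjoint
#' @export
setMethod("dictAdjoint",
          signature(dict = "RedundantFourierDictionary", signal = "numeric"),
          function(dict, signal) {
  dictAdjoint(dict, as.complex(signal))
})

#' @rdname dictAdjoint
#' @export
setMethod("dictAdjoint",
          signature(dict = "RedundantFourierDictionary",
                    signal = "DigitalSignal"),
          function(dict, signal) {
  dictAdjoint(dict, as.complex(samples(signal)))
})

#' @rdname spectralResolution
#' @export
setMethod("spectralResolution", "DigitalSignal",
          function(object) object@fs / length(object@samples))

#' @rdname spectralResolution
#' @export
setMethod("spectralResolution", "RedundantFourierDictionary",
          function(object) object@fs / object@nAtoms)

#' @rdname oneSidedAmplitude
#' @export
setMethod("oneSidedAmplitude", "SparseCoefficients", function(object) {
  foldOneSided(Mod(object@values))
})

## fold a length-K modulus vector onto the positive half k = 0..K/2:
## interior bins represent a conjugate pair, DC and Nyquist stand alone
foldOneSided <- function(m) {
  K <- length(m)
  half <- K %/% 2
  a <- 2 * m[seq_len(half + 1)]
  a[1] <- m[1]
  if (K %% 2 == 0) a[half + 1] <- m[half + 1]
  a
}

#' Tabulate a sparse spectrum
#'
#' Positive-frequency view of a coefficient vector as a data.frame with one
#' row per bin `k = 0..K/2`.
#'
#' @param coeffs a [SparseCoefficients-class].
#' @return data.frame with columns `bin_index` (0-based), `frequency_hz`,
#'   `real`, `imag`, `one_sided_amplitude`.
#' @export
spectrumTable <- function(coeffs) {
  stopifnot(is(coeffs, "SparseCoefficients"))
  K <- length(coeffs@values)
  half <- K %/% 2
  v <- coeffs@values[seq_len(half + 1)]
  data.frame(bin_index = 0:half,
             frequency_hz = (0:half) * coeffs@dict@fs / K,
             real = Re(v), imag = Im(v),
             one_sided_amplitude = oneSidedAmplitude(coeffs))
}

#' Export a sparse spectrum as CSV
#'
#' Writes the [spectrumTable()] of `coeffs` to `path`.
#'
#' @param coeffs a [SparseCoefficients-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSpectrum <- function(coeffs, path) {
  utils::write.csv(spectrumTable(coeffs), path, row.names = FALSE)
  invisible(path)
}
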