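#' Sample values of a digital signal
#'
#' @param object a [DigitalSignal-class] object.
#' @return Numeric vector of samples.
#' @export
setGeneric("samples", function(object) standardGeneric("samples"))

#' Sampling frequency in Hz
#'
#' @param object an object carrying a sampling frequency (a
#'   [DigitalSignal-class] or a [RedundantFourierDictionary-class]).
#' @return Sampling frequency in Hz.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' Number of time-domain samples
#'
#' @param object a [DigitalSignal-class] or
#'   [RedundantFourierDictionary-class].
#' @return Integer count of samples N.
#' @export
setGeneric("nSamples", function(object) standardGeneric("nSamples"))

#' Number of dictionary atoms
#'
#' @param object a [RedundantFourierDictionary-class] or
#'   [SparseCoefficients-class].
#' @return Integer count of atoms K.
#' @export
setGeneric("nAtoms", function(object) standardGeneric("nAtoms"))

#' Redundancy factor Q = K/N of a dictionary
#'
#' @param object a [RedundantFourierDictionary-class].
#' @return The redundancy factor, a positive integer.
#' @export
setGeneric("redundancy", function(object) standardGeneric("redundancy"))

#' Tight-frame constant of a dictionary
#'
#' For the unnormalized complex-exponential atoms used here the
#' synthesis-analysis composition satisfies `A A^H = p I` with `p = K`.
#'
#' @param object a [RedundantFourierDictionary-class].
#' @return The frame constant p (equal to the number of atoms K).
#' @export
setGeneric("frameConstant", function(object) standardGeneric("frameConstant"))

#' Frequency grid in Hz
#'
#' @param object a [RedundantFourierDictionary-class] or
#'   [SparseCoefficients-class].
#' @return Numeric vector of atom frequencies `k * fs / K`, `k = 0..K-1`.
#' @export
setGeneric("frequencyGrid", function(object) standardGeneric("frequencyGrid"))

#' Frequency resolution in Hz per spectral line
#'
#' `fs/N` for a signal analysed with the orthonormal Fourier basis, `fs/K`
#' for the grid of a redundant dictionary.
#'
#' @param object a [DigitalSignal-class] or
#'   [RedundantFourierDictionary-class].
#' @return Spacing between adjacent spectral lines in Hz.
#' @export
setGeneric("spectralResolution",
           function(object) standardGeneric("spectralResolution"))

#' Synthesis operator of a redundant Fourier dictionary
#'
#' Computes `A x`, the complex time-domain synthesis of a length-K
#' coefficient vector, via a length-K inverse FFT truncated to the first N
#' samples. The result is complex; take the real part when a real waveform
#' is wanted (real inputs are represented by conjugate-symmetric
#' coefficients).
#'
#' @param dict a [RedundantFourierDictionary-class].
#' @param coeffs a complex vector of length K or a
#'   [SparseCoefficients-class].
#' @return Complex vector of length N.
#' @export
setGeneric("dictApply", function(dict, coeffs) standardGeneric("dictApply"))

#' Analysis (adjoint) operator of a redundant Fourier dictionary
#'
#' Computes `A^H y` by zero-padding the length-N signal to length K and
#' taking a forward FFT.
#'
#' @param dict a [RedundantFourierDictionary-class].
#' @param signal a [DigitalSignal-class] or numeric/complex vector of
#'   length N.
#' @return Complex coefficient vector of length K.
#' @export
setGeneric("dictAdjoint", function(dict, signal) standardGeneric("dictAdjoint"))

#' Coefficient values of a sparse spectrum
#'
#' @param object a [SparseCoefficients-class].
#' @return Complex vector of length K.
#' @export
setGeneric("coefValues", function(object) standardGeneric("coefValues"))

#' Source dictionary of a coefficient vector
#'
#' @param object a [SparseCoefficients-class].
#' @return The [RedundantFourierDictionary-class] the coefficients refer to.
#' @export
setGeneric("dictionary", function(object) standardGeneric("dictionary"))

#' One-sided amplitude view of a sparse spectrum
#'
#' Maps the complex coefficients on the positive-frequency half of the grid
#' (`k = 0..K/2`) to physical amplitudes: `2|x_k|` for `0 < k < K/2` (each
#' positive-frequency line stands for itself plus its conjugate partner) and
#' `|x_k|` at DC and Nyquist. Under this convention a unit-amplitude cosine
#' at a grid frequency reads close to 1.
#'
#' @param object a [SparseCoefficients-class].
#' @return Numeric vector of length `K/2 + 1`.
#' @export
setGeneric("oneSidedAmplitude",
           function(object) standardGeneric("oneSidedAmplitude"))

#' Denoised signal of a detection result
#'
#' @param object a [DetectionResult-class].
#' @return The denoised [DigitalSignal-class].
#' @export
setGeneric("denoised", function(object) standardGeneric("denoised"))

#' Compensation (reconstructed interference) signal
#'
#' @param object a [DetectionResult-class].
#' @return The compensation [DigitalSignal-class] that was subtracted.
#' @export
setGeneric("compensation", function(object) standardGeneric("compensation"))

#' Dominant spectral lines of a detection result
#'
#' @param object a [DetectionResult-class].
#' @return A data.frame of spectral lines (bin, frequency, coefficient,
#'   amplitude).
#' @export
setGeneric("dominantLines", function(object) standardGeneric("dominantLines"))

#' Spectral lines attributed to powerline interference
#'
#' @param object a [DetectionResult-class].
#' @return A data.frame, a subset of [dominantLines()].
#' @export
setGeneric("pliLines", function(object) standardGeneric("pliLines"))

#' Per-iteration loss history of the solver
#'
#' @param object a [DetectionResult-class].
#' @return Numeric vector of `||lambda (*) x^(k)||_1` values.
#' @export
setGeneric("lossHistory", function(object) standardGeneric("lossHistory"))
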