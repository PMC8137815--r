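#' @include AllClasses.R
NULL

#' Complex soft thresholding (proximal operator of the l1 norm)
#'
#' Shrinks each coefficient's magnitude by `min(T, |c|)` while preserving
#' its phase: `c * max(1 - T/|c|, 0)`, with 0 returned where `|c| = 0`.
#' This is the exact minimizer of `T*|z| + 0.5*|z - c|^2` over the complex
#' plane, the operation the l1-penalized objective calls for at each
#' iteration.
#'
#' @param coeffs complex (or numeric) vector.
#' @param threshold nonnegative scalar or vector of matching length.
#' @return Complex vector of the same length as `coeffs`.
#' @examples
#' softThreshold(5, 2)            # 3
#' softThreshold(3 * exp(1i * pi / 4), 3)  # 0: fully annihilated
#' softThreshold(4i, 1)           # 3i: phase preserved
#' @export
softThreshold <- function(coeffs, threshold) {
  if (any(!is.finite(threshold)) || any(threshold < 0))
    stop("threshold must be nonnegative and finite")
  if (length(threshold) != 1L && length(threshold) != length(coeffs))
    stop("threshold must be a scalar or match the coefficient length")
  coeffs <- as.complex(coeffs)
  m <- Mod(coeffs)
  coeffs * pmax(1 - threshold / pmax(m, .Machine$double.xmin), 0)
}

#' Effective threshold weight for a given problem
#'
#' Resolves a [SolverSettings-class] lambda to absolute units: in
#' `"relative-to-max"` mode the weight is multiplied by the magnitude of
#' the largest back-projected coefficient `max |A^H y| / p` of the input,
#' making the setting scale-invariant; in `"absolute"` mode it is returned
#' unchanged.
#'
#' @param settings a [SolverSettings-class].
#' @param dict a [RedundantFourierDictionary-class].
#' @param y a [DigitalSignal-class] or numeric vector of length N.
#' @return Numeric scalar or length-K vector lambda in absolute units.
#' @export
effectiveLambda <- function(settings, dict, y) {
  stopifnot(is(settings, "SolverSettings"))
  validObject(settings)
  if (settings@lambdaMode == "absolute") return(settings@lambdaWeight)
  scale <- max(Mod(dictAdjoint(dict, y))) / frameConstant(dict)
  settings@lambdaWeight * scale
}

#' One SALSA iteration
#'
#' Advances the split augmented Lagrangian shrinkage iteration for the
#' basis-pursuit-denoising objective
#' `argmin_x 0.5*||y - Ax||_2^2 + ||lambda (*) x||_1`
#' by one step. With the splitting `u = x` the alternating scheme is
#'
#' \preformatted{
#'   u <- soft(x + d, lambda/mu)
#'   x <- (u - d) + A^H (y - A (u - d)) / (mu + p)
#'   d <- x - (u - d)
#' }
#'
#' where the x-update is the exact penalized least-squares minimizer
#' `(A^H A + mu I)^{-1} (A^H y + mu (u - d))` rewritten through the
#' tight-frame identity `A A^H = p I`, and d accumulates the scaled
#' Lagrange multiplier. Both operator applications run as length-K FFTs.
#'
#' @param state a [SalsaState-class] (slots x, d of length K).
#' @param y a [DigitalSignal-class] or numeric vector of length N.
#' @param dict a [RedundantFourierDictionary-class].
#' @param settings a [SolverSettings-class].
#' @param lambda optional pre-resolved absolute lambda; computed from
#'   `settings` via [effectiveLambda()] when missing.
#' @return The advanced [SalsaState-class].
#' @seealso [salsaBpdn()] for the full solver loop.
#' @export
salsaStep <- function(state, y, dict, settings, lambda = NULL) {
  stopifnot(is(state, "SalsaState"))
  K <- nAtoms(dict)
  if (length(state@x) != K || length(state@d) != K)
    stop("state dimensions must match the dictionary's atom count K")
  if (is(y, "DigitalSignal")) y <- samples(y)
  if (length(y) != nSamples(dict))
    stop("signal length must equal the dictionary's nSamples N")
  if (is.null(lambda)) lambda <- effectiveLambda(settings, dict, y)
  mu <- settings@mu
  p <- frameConstant(dict)
  u <- softThreshold(state@x + state@d, lambda / mu)
  b <- u - state@d
  x <- b + dictAdjoint(dict, y - dictApply(dict, b)) / (mu + p)
  new("SalsaState", x = x, d = x - b, iter = state@iter + 1L)
}

#' Sparse Fourier spectrum via SALSA basis-pursuit denoising
#'
#' Runs the SALSA iteration (see [salsaStep()]) for `maxIter` iterations
#' (or until the relative loss change drops below `relTol`, when set),
#' recording the loss `||lambda (*) x^(k)||_1` at every iteration. The
#' iteration starts from the minimum-norm representation
#' `x^(0) = A^H y / p` with `d^(0) = 0`. The solver is fully deterministic:
#' identical inputs and settings give bit-identical output.
#'
#' @param y a [DigitalSignal-class] or numeric vector of length N.
#' @param dict a [RedundantFourierDictionary-class].
#' @param settings a [SolverSettings-class]; see [solverSettings()].
#' @return A list with elements `coefficients` (a
#'   [SparseCoefficients-class]), `lossHistory` (numeric, one value per
#'   iteration run), `lambda` (the absolute threshold weight used) and
#'   `state` (the final [SalsaState-class], usable to warm-restart via
#'   [salsaStep()]).
#' @examples
#' sig <- generatePli(harmonicParams(1, 50.15, pi / 3), 1000, 1000)
#' dict <- buildDictionary(1000, 10, 1000)
#' fit <- salsaBpdn(sig, dict, solverSettings(maxIter = 100))
#' @export
salsaBpdn <- function(y, dict, settings = solverSettings()) {
  stopifnot(is(settings, "SolverSettings"))
  validObject(settings)
  if (is(y, "DigitalSignal")) y <- samples(y)
  if (length(y) != nSamples(dict))
    stop("signal length must equal the dictionary's nSamples N")
  K <- nAtoms(dict)
  p <- frameConstant(dict)
  lambda <- effectiveLambda(settings, dict, y)
  state <- new("SalsaState",
               x = dictAdjoint(dict, y) / p,
               d = complex(K), iter = 0L)
  loss <- numeric(settings@maxIter)
  ran <- 0L
  for (k in seq_len(settings@maxIter)) {
    state <- salsaStep(state, y, dict, settings, lambda = lambda)
    loss[k] <- lossValue(state@x, lambda)
    ran <- k
    if (!is.na(settings@relTol) && k > 1L) {
      ref <- max(loss[k - 1L], .Machine$double.xmin)
      if (abs(loss[k] - loss[k - 1L]) / ref < settings@relTol) break
    }
  }
  list(coefficients = sparseCoefficients(state@x, dict),
       lossHistory = loss[seq_len(ran)],
       lambda = lambda,
       state = state)
}

#' Loss value of a coefficient vector
#'
#' The l1 norm of the elementwise product `lambda (*) x`, using the complex
#' modulus: `sum_i |lambda_i * x_i|`. A scalar lambda is broadcast.
#'
#' @param coeffs complex vector.
#' @param lambda nonnegative scalar or vector of matching length.
#' @return Nonnegative scalar.
#' @examples
#' lossValue(c(3, -4i), 1)  # 7
#' @export
lossValue <- function(coeffs, lambda) {
  if (length(lambda) != 1L && length(lambda) != length(coeffs))
    stop("lambda must be a scalar or match the coefficient length")
  sum(Mod(lambda * as.complex(coeffs)))
}

#' Export a loss history as CSV
#'
#' @param loss numeric vector of per-iteration loss values.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeLossHistory <- function(loss, path) {
  utils::write.csv(data.frame(iteration = seq_along(loss), loss = loss),
                   path, row.names = FALSE)
  invisible(path)
}
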