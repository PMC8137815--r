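# Independent brute-force oracles used to validate the FFT-based fast paths
# and the solver. Everything here is dense, direct and slow on purpose.

# explicit N x K dictionary matrix: atom k is exp(2i*pi*k*n/K), n = 0..N-1
denseDict <- function(N, K) {
  outer(0:(N - 1), 0:(K - 1), function(n, k) exp(2i * pi * k * n / K))
}

# direct O(N^2) DFT, orthonormal scaling
denseOrthoDft <- function(x) {
  N <- length(x)
  B <- outer(0:(N - 1), 0:(N - 1), function(n, k) exp(-2i * pi * k * n / N))
  as.vector(B %*% x) / sqrt(N)
}

# grid-search minimizer of T*|z| + 0.5*|z - c|^2 over a complex square grid
proxGridSearch <- function(c0, T, lim = 5, nGrid = 2001) {
  g <- seq(-lim, lim, length.out = nGrid)
  re <- rep(g, times = nGrid)
  im <- rep(g, each = nGrid)
  z <- complex(real = re, imaginary = im)
  obj <- T * Mod(z) + 0.5 * Mod(z - c0)^2
  z[which.min(obj)]
}

# exhaustive best-subset least squares over all 1-atom and 2-atom supports;
# returns the 0-based atom indices of the best fit
exhaustiveSupport <- function(y, Phi, maxAtoms = 2) {
  K <- ncol(Phi)
  best <- list(rss = Inf, support = integer())
  trials <- c(lapply(seq_len(K), identity),
              utils::combn(K, maxAtoms, simplify = FALSE))
  for (idx in trials) {
    B <- Phi[, idx, drop = FALSE]
    coef <- qr.solve(Conj(t(B)) %*% B, Conj(t(B)) %*% y)
    rss <- sum(Mod(y - B %*% coef)^2)
    if (rss < best$rss - 1e-12) best <- list(rss = rss, support = idx - 1L)
  }
  best$support
}

# the off-grid simulation conditions used throughout: a unit cosine at
# 50.15 Hz with phase pi/3, 1000 samples at 1000 Hz, Q = 10 dictionary
simSignal <- function() {
  generatePli(harmonicParams(1, 50.15, pi / 3), 1000, 1000)
}

simDictionary <- function() {
  buildDictionary(1000, 10, 1000)
}

relErr <- function(a, b) {
  sqrt(sum(Mod(a - b)^2) / sum(Mod(b)^2))
}
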