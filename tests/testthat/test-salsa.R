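test_that("soft thresholding shrinks magnitudes and preserves phase", {
  expect_equal(softThreshold(5, 2), complex(real = 3))
  expect_equal(softThreshold(3 * exp(1i * pi / 4), 3), complex(real = 0))
  expect_equal(softThreshold(4i, 1), 3i)
  # magnitude shrinks by exactly min(T, |c|), phase untouched
  set.seed(4)
  c0 <- complex(real = rnorm(50), imaginary = rnorm(50))
  out <- softThreshold(c0, 0.8)
  expect_equal(Mod(out), pmax(Mod(c0) - 0.8, 0), tolerance = 1e-12)
  nz <- Mod(out) > 0
  expect_equal(Arg(out[nz]), Arg(c0[nz]), tolerance = 1e-12)
  expect_error(softThreshold(c0, -1), "threshold")
  expect_error(softThreshold(c0, c(1, 2)), "threshold")
})

test_that("soft thresholding is the proximal operator of the l1 norm", {
  # brute-force grid search over the complex plane
  for (cs in list(list(c0 = 4i, T = 1), list(c0 = -2 + 1.5i, T = 0.6))) {
    zGrid <- proxGridSearch(cs$c0, cs$T)
    expect_lt(Mod(softThreshold(cs$c0, cs$T) - zGrid), 2 * 10 / 2001)
  }
})

test_that("one SALSA step equals its dense-matrix transliteration", {
  N <- 8L; M <- 2L; K <- 16L
  dict <- buildDictionary(N, M, N)
  Phi <- denseDict(N, K)
  p <- K
  set.seed(5)
  for (i in 1:5) {
    y <- rnorm(N)
    x0 <- complex(real = rnorm(K), imaginary = rnorm(K))
    d0 <- complex(real = rnorm(K), imaginary = rnorm(K))
    st <- new("SalsaState", x = x0, d = d0, iter = 0L)
    settings <- solverSettings(lambda = 0.3, mu = 0.7,
                               lambdaMode = "absolute")
    out <- salsaStep(st, y, dict, settings)

    # dense transliteration of the same update equations
    u <- softThreshold(x0 + d0, 0.3 / 0.7)
    b <- u - d0
    xNew <- b + as.vector(Conj(t(Phi)) %*% (y - Phi %*% b)) / (0.7 + p)
    expect_lt(relErr(out@x, xNew), 1e-10)
    expect_lt(relErr(out@d, xNew - b), 1e-10)
    # structural identity: x = d_new + (u - d_old)
    expect_lt(relErr(out@x, out@d + b), 1e-12)
  }
  # zero input and zero state form a fixed point
  st0 <- new("SalsaState", x = complex(K), d = complex(K), iter = 0L)
  out0 <- salsaStep(st0, numeric(N), dict, solverSettings())
  expect_identical(out0@x, complex(K))
  expect_identical(out0@d, complex(K))
  expect_error(salsaStep(new("SalsaState", x = complex(8), d = complex(8),
                             iter = 0L), numeric(N), dict, solverSettings()),
               "dimensions")
})

test_that("the solver is deterministic and zero in gives zero out", {
  sig <- simSignal(); dict <- simDictionary()
  s <- solverSettings(maxIter = 20)
  a <- salsaBpdn(sig, dict, s)
  b <- salsaBpdn(sig, dict, s)
  expect_identical(a$coefficients@values, b$coefficients@values)
  expect_identical(a$lossHistory, b$lossHistory)

  z <- salsaBpdn(digitalSignal(numeric(100), 100),
                 buildDictionary(100, 2, 100), solverSettings(maxIter = 10))
  expect_identical(coefValues(z$coefficients), complex(200))
  expect_identical(z$lossHistory, numeric(10))
})

test_that("the loss history decreases and flattens", {
  fit <- salsaBpdn(simSignal(), simDictionary(), solverSettings(maxIter = 100))
  loss <- fit$lossHistory
  expect_length(loss, 100)
  expect_true(all(loss >= 0))
  # steep early descent, then slow compaction
  expect_lt(loss[10], 0.5 * loss[1])
  expect_lt(loss[100], loss[10])
  expect_lt(loss[10] - loss[100], 0.25 * loss[10])
  # near-monotone: any ADMM uptick is tiny relative to the loss level
  up <- diff(loss)[-(1:4)]
  expect_lt(max(c(up, 0)), 1e-2 * loss[5])
})

test_that("early stopping truncates the iteration when requested", {
  sig <- simSignal(); dict <- simDictionary()
  full <- salsaBpdn(sig, dict, solverSettings(maxIter = 200))
  early <- salsaBpdn(sig, dict, solverSettings(maxIter = 200, relTol = 1e-3))
  expect_lt(length(early$lossHistory), 200)
  expect_identical(full$lossHistory[seq_along(early$lossHistory)],
                   early$lossHistory)
})

test_that("a grid-frequency cosine converges to a 1-sparse half-spectrum", {
  sig <- generatePli(harmonicParams(1, 50, 0), 1000, 1000)
  dict <- simDictionary()
  fit <- salsaBpdn(sig, dict, solverSettings(maxIter = 1000))
  a <- oneSidedAmplitude(fit$coefficients)
  expect_identical(which.max(a) - 1L, 500L)        # bin of 50.0 Hz
  expect_lt(sort(a, decreasing = TRUE)[2], 1e-3 * max(a))
  expect_equal(max(a), 1, tolerance = 0.05)        # unit cosine reads ~1

  # fixed point: ten further iterations barely move the converged solution
  st2 <- fit$state
  for (i in 1:10) st2 <- salsaStep(st2, sig, dict, solverSettings(),
                                   lambda = fit$lambda)
  expect_lt(relErr(st2@x, fit$state@x), 1e-6)
})

test_that("the synthesis of the full solution stays inside a tight data ball", {
  fit <- salsaBpdn(simSignal(), simDictionary(), solverSettings(maxIter = 100))
  yhat <- Re(dictApply(simDictionary(), fit$coefficients))
  expect_lt(relErr(yhat, samples(simSignal())), 0.01)
})

test_that("the solver finds the exhaustive-search support on a tiny instance", {
  N <- 8L; K <- 16L
  dict <- buildDictionary(N, 2, N)
  Phi <- denseDict(N, K)
  # 1-sparse truth in the real sense: one atom plus its conjugate partner
  y <- Re(0.8 * Phi[, 6])                 # atom k = 5 (0-based), partner 11
  fit <- salsaBpdn(digitalSignal(y, N), dict,
                   solverSettings(maxIter = 500))
  solver <- sort(order(Mod(coefValues(fit$coefficients)),
                       decreasing = TRUE)[1:2]) - 1L
  oracle <- sort(exhaustiveSupport(y, Phi))
  expect_identical(as.integer(solver), as.integer(oracle))
})

test_that("loss values are l1 norms of the weighted coefficients", {
  expect_identical(lossValue(complex(10), 3), 0)
  expect_equal(lossValue(c(3, -4i), 1), 7)
  set.seed(6)
  x <- complex(real = rnorm(100), imaginary = rnorm(100))
  expect_equal(lossValue(x, 0.5), 0.5 * sum(Mod(x)))
  w <- runif(100)
  expect_equal(lossValue(x, w), sum(w * Mod(x)))
  expect_error(lossValue(x, c(1, 2)), "lambda")
})
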