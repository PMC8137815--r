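test_that("dominant-line selection thresholds, sorts and breaks ties", {
  dict <- buildDictionary(8, 2, 16)   # K = 16, grid step 1 Hz
  v <- complex(16)
  v[3] <- 0.5        # bin 2, amplitude 1.0
  v[5] <- 0.25       # bin 4, amplitude 0.5
  v[7] <- 0.25       # bin 6, amplitude 0.5 (tie with bin 4)
  v[9] <- 0.004      # bin 8 = Nyquist, amplitude 0.004: below 1%
  cf <- sparseCoefficients(v, dict)
  lines <- findDominantLines(cf, 0.01)
  expect_identical(lines$bin, c(2L, 4L, 6L))        # ties by ascending freq
  expect_identical(lines$frequency, c(2, 4, 6))
  expect_identical(lines$amplitude, c(1, 0.5, 0.5))

  # threshold at the maximum keeps only the argmax
  expect_identical(findDominantLines(cf, 1)$bin, 2L)
  # all-zero spectrum: empty, not an error
  expect_identical(nrow(findDominantLines(sparseCoefficients(complex(16),
                                                             dict))), 0L)
  expect_error(findDominantLines(cf, 0), "thresholdFrac")
})

test_that("powerline-band selection keeps in-band lines in order", {
  lines <- data.frame(bin = c(1L, 2L, 3L),
                      frequency = c(49.95, 49.96, 76.0),
                      coefficient = complex(3, real = 1),
                      amplitude = c(3, 2, 1))
  sel <- selectPliLines(lines, 50, 2)
  expect_identical(sel$frequency, c(49.95, 49.96))
  expect_identical(nrow(selectPliLines(lines[0, ], 50, 2)), 0L)
  # boundary inclusion at half-width zero
  at50 <- data.frame(bin = 5L, frequency = 50, coefficient = 1 + 0i,
                     amplitude = 1)
  expect_identical(nrow(selectPliLines(at50, 50, 0)), 1L)
  # several disjoint bands at once
  both <- selectPliLines(lines, c(50, 76), 2)
  expect_identical(both$frequency, c(49.95, 49.96, 76.0))
  expect_error(selectPliLines(lines, -50, 2), "nominalFreq")
})

test_that("reconstruction from selected lines restores a grid cosine", {
  sig <- generatePli(harmonicParams(1, 50, 0.3), 1000, 1000)
  dict <- simDictionary()
  fit <- salsaBpdn(sig, dict, solverSettings(maxIter = 1000))
  top <- findDominantLines(fit$coefficients, 1)   # the single argmax line
  rec <- reconstructComponent(top, dict)
  expect_lt(relErr(samples(rec), samples(sig)), 1e-3)

  # empty selection synthesizes silence
  expect_identical(samples(reconstructComponent(top[0, ], dict)),
                   numeric(1000))
  bad <- top; bad$bin <- nAtoms(dict)  # beyond K/2
  expect_error(reconstructComponent(bad, dict), "out of range")
})

test_that("removing pure interference leaves almost nothing behind", {
  res <- removePli(simSignal())
  expect_s4_class(res, "DetectionResult")
  resid <- sqrt(sum(samples(denoised(res))^2) /
                  sum(samples(res@input)^2))
  expect_lt(resid, 0.01)
  # conservation holds exactly, elementwise
  expect_identical(samples(denoised(res)),
                   samples(res@input) - samples(compensation(res)))
})

test_that("off-band features survive interference removal untouched", {
  base <- generatePli(harmonicParams(1, 10, 0), 1000, 1000)
  pli <- generatePli(harmonicParams(0.5, 50, 0), 1000, 1000)
  corrupted <- digitalSignal(samples(base) + samples(pli), 1000)
  res <- removePli(corrupted)

  ampAt <- function(sig, f) 2 * Mod(fourierCoefficientAt(sig, f)) / 1000
  expect_lt(abs(ampAt(denoised(res), 10) - ampAt(base, 10)) / ampAt(base, 10),
            0.01)
  expect_lt(ampAt(denoised(res), 50) / ampAt(pli, 50), 0.01)

  # every removed line sits inside the band, and the compensation is
  # synthesized from those lines only
  expect_true(all(abs(pliLines(res)$frequency - 50) <= 2))
  dict <- buildDictionary(1000, 10, 1000)
  expect_identical(samples(compensation(res)),
                   samples(reconstructComponent(pliLines(res), dict)))
})

test_that("feature preservation holds for noisy off-band tones", {
  for (seed in c(1, 2)) {
    sig <- generateMixture(list(harmonicParams(1, 21.3),
                                harmonicParams(1, 50.15, 1)),
                           backgroundSd = 0.05, seed = seed,
                           nSamples = 1000, fs = 1000)
    res <- removePli(sig)
    est <- estimateHarmonicParams(denoised(res))
    expect_lt(abs(est@frequency - 21.3), 0.05)
    expect_lt(abs(est@amplitude - 1), 0.02)
  }
})

test_that("a signal without in-band content passes through unchanged", {
  clean <- generatePli(harmonicParams(1, 10, 0), 1000, 1000)
  expect_warning(res <- removePli(clean), "powerline band")
  expect_identical(samples(denoised(res)), samples(clean))
  expect_identical(samples(compensation(res)), numeric(1000))
})

test_that("interference removal is approximately idempotent", {
  sig <- generateMixture(list(harmonicParams(1, 10),
                              harmonicParams(0.5, 50.15, 1)),
                         backgroundSd = 0.05, seed = 3,
                         nSamples = 1000, fs = 1000)
  first <- removePli(sig)
  second <- suppressWarnings(removePli(denoised(first)))
  expect_lt(relErr(samples(denoised(second)), samples(denoised(first))),
            0.005)
})

test_that("harmonic parameters are recovered from waveforms", {
  # on-grid case is exact
  est <- estimateHarmonicParams(generatePli(harmonicParams(2, 50, 0),
                                            1000, 1000))
  expect_equal(est@amplitude, 2, tolerance = 1e-6)
  expect_equal(est@frequency, 50, tolerance = 1e-6)
  expect_equal(est@phase, 0, tolerance = 1e-6)

  # randomized off-grid recovery sweep
  set.seed(12)
  for (i in 1:20) {
    a <- runif(1, 0.5, 2)
    f <- runif(1, 45, 55)
    ph <- runif(1, -pi, pi)
    est <- estimateHarmonicParams(generatePli(harmonicParams(a, f, ph),
                                              1000, 1000))
    expect_lt(abs(est@frequency - f), 0.05)
    expect_lt(abs(est@amplitude - a) / a, 0.02)
    dphi <- abs(est@phase - ph)
    expect_lt(min(dphi, 2 * pi - dphi), 0.05)
  }

  expect_error(estimateHarmonicParams(digitalSignal(numeric(10), 100)),
               "all-zero")
})

test_that("the reconstructed interference matches its known generator", {
  res <- removePli(simSignal())
  est <- estimateHarmonicParams(compensation(res))
  expect_lt(abs(est@frequency - 50.15), 0.05)
  expect_lt(abs(est@amplitude - 1), 0.02)
  expect_lt(abs(est@phase - pi / 3), 0.05)
})
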