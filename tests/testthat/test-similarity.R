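mkPair <- function() list(
  a = Spectrum(c(50, 100), c(100, 50), id = "a"),
  b = Spectrum(c(50, 100), c(50, 100), id = "b")
)

test_that("alignUnion pads missing m/z with zero intensity", {
  a <- Spectrum(83, 100); b <- Spectrum(126, 100)
  u <- alignUnion(a, b)
  expect_equal(u$mz, c(83, 126))
  expect_equal(u$intensityA, c(100, 0))
  expect_equal(u$intensityB, c(0, 100))

  p <- mkPair()
  u2 <- alignUnion(p$a, p$b)
  expect_equal(u2$intensityA, c(100, 50))
  expect_equal(u2$intensityB, c(50, 100))

  self <- alignUnion(p$a, p$a)
  expect_equal(self$intensityA, self$intensityB)

  expect_error(alignUnion(Spectrum(50.4, 100), b), "nominal-binned")
})

test_that("cosineScore matches hand-evaluated cases and bounds", {
  p <- mkPair()
  ## dot = 100*50 + 50*100 = 10000; norms = sqrt(12500) each -> 0.8 * 1000
  expect_equal(cosineScore(p$a, p$b), 800)
  expect_equal(cosineScore(p$a, p$a), 1000)
  expect_equal(cosineScore(Spectrum(83, 100), Spectrum(126, 100)), 0)
})

test_that("weightedIntensity follows the power law with zero preserved", {
  expect_equal(weightedIntensity(1, 1), 1)
  expect_equal(weightedIntensity(0, 77), 0)
  expect_equal(weightedIntensity(100, 100), 100^0.6 * 100^3)
  expect_equal(weightedIntensity(100, 100), 1.5849e7, tolerance = 1e-4)
})

test_that("wdotScore matches hand evaluation and its invariants", {
  p <- mkPair()
  expect_equal(wdotScore(p$a, p$b),
               bruteForceScore(c(50, 100), c(100, 50),
                               c(50, 100), c(50, 100)),
               tolerance = 1e-12)
  expect_equal(wdotScore(p$a, p$b), 994.5, tolerance = 1e-3)
  expect_equal(wdotScore(p$a, p$a), 1000)
  ## one shared mz: 1-D parallel weighted vectors regardless of intensity
  expect_equal(wdotScore(Spectrum(90, 100), Spectrum(90, 37)), 1000)
  ## symmetry + rescaling invariance over random pairs
  set.seed(11)
  for (i in 1:25) {
    x <- randomPeakList(); y <- randomPeakList()
    sx <- asSpectrum(x); sy <- asSpectrum(y)
    expect_equal(wdotScore(sx, sy), wdotScore(sy, sx), tolerance = 1e-12)
    sxk <- Spectrum(x$mz, x$intensity * 7.3)
    expect_equal(wdotScore(sxk, sy), wdotScore(sx, sy), tolerance = 1e-9)
    sc <- wdotScore(sx, sy)
    expect_gte(sc, 0); expect_lte(sc, 1000 + 1e-9)
  }
})

test_that("scores agree with the brute-force oracle on random small spectra", {
  set.seed(21)
  for (i in 1:200) {
    x <- randomPeakList(); y <- randomPeakList()
    expect_equal(wdotScore(asSpectrum(x), asSpectrum(y)),
                 bruteForceScore(x$mz, x$intensity, y$mz, y$intensity),
                 tolerance = 1e-9)
    expect_equal(cosineScore(asSpectrum(x), asSpectrum(y)),
                 bruteForceScore(x$mz, x$intensity, y$mz, y$intensity,
                                 weighted = FALSE),
                 tolerance = 1e-9)
  }
})

test_that("score bands use strict lower bounds per scheme", {
  expect_equal(scoreBand(c(810, 801, 800, 650, 601, 600, 500, 401, 400, 100)),
               c("excellent", "excellent", "good", "good", "good", "fair",
                 "fair", "fair", "poor", "poor"))
  expect_equal(scoreBand(c(860, 850, 700, 600, 100), scheme = "text"),
               c("good", "moderate", "moderate", "poor", "poor"))
})

test_that("similarityMatrix equals elementwise pairwise scores", {
  set.seed(33)
  entries <- lapply(1:3, function(i) asSpectrum(randomPeakList(), id = paste0("s", i)))
  lib <- SpectrumLibrary(entries)
  m <- similarityMatrix(lib, lib)
  expect_equal(unname(diag(m)), rep(1000, 3))
  expect_equal(m, t(m))
  for (i in 1:3) for (j in 1:3)
    expect_equal(m[i, j], wdotScore(entries[[i]], entries[[j]]),
                 tolerance = 1e-12)
  expect_error(similarityMatrix(SpectrumLibrary(), lib), "non-empty")
})

test_that("median score degrades monotonically with increasing dropout", {
  spec <- defaultClassSpecs()$xanthines
  ref <- generateReferenceSpectrum(spec, seed = 77)
  med <- vapply(c(0, 0.2, 0.5, 0.9), function(p) {
    sc <- vapply(1:100, function(i)
      wdotScore(perturbSpectrum(ref, perturbationConfig(dropoutProb = p),
                                seed = 1000 + i), ref),
      numeric(1))
    stats::median(sc)
  }, numeric(1))
  expect_true(all(diff(med) <= 0))
  expect_equal(med[1], 1000)
})
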