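test_that("parseMSP handles empty input and both peak dialects", {
  expect_equal(length(parseMSP("")), 0L)

  space <- "Name: a\nMW: 126\nNum Peaks: 2\n83 30\n126 100\n"
  colon <- "Name: a\nMW: 126\nNum Peaks: 2\n83:30; 126:100;\n"
  libS <- parseMSP(space); libC <- parseMSP(colon)
  expect_equal(peakTable(libS[["a"]]), peakTable(libC[["a"]]))
  expect_equal(peakMz(libS[["a"]]), c(83, 126))
  expect_equal(nominalMw(libS[["a"]]), 126)
})

test_that("parseMSP validates peak counts and malformed lines", {
  bad <- "Name: b\nMW: 100\nNum Peaks: 3\n50 10\n100 100\n"
  expect_error(parseMSP(bad), "'Num Peaks: 3' but 2")
  mal <- "Name: b\nNum Peaks: 1\nfifty ten\n"
  expect_error(parseMSP(mal), "malformed peak line")
})

test_that("parseMSP infers a missing MW from the largest m/z and flags it", {
  lib <- parseMSP("Name: c\nNum Peaks: 2\n50 20\n120 100\n")
  s <- lib[["c"]]
  expect_equal(nominalMw(s), 120)
  expect_true(s@mwInferred)
})

test_that("parseMSP reads the subclass tag out of the comment field", {
  lib <- parseMSP(
    "Name: g\nMW: 151\nComment: origin=synthetic subclass=guanines\nNum Peaks: 1\n151 100\n")
  expect_equal(subclassLabel(lib[["g"]]), "guanines")
})

test_that("write/parse round-trips libraries, including generator output", {
  s1 <- Spectrum(c(43, 126), c(10, 100), id = "s1", name = "one",
                 nominalMw = 126, subclass = "pyrimidines")
  s2 <- Spectrum(c(55, 83, 140), c(12.5, 40, 100), id = "s2", name = "two",
                 nominalMw = 140)
  lib <- SpectrumLibrary(list(s1, s2), sourceLabel = "x")
  txt <- writeMSP(lib)
  ## ordering contract: both peak lines present, ascending mz
  expect_true(grepl("43 10\n126 100", txt, fixed = TRUE))
  back <- parseMSP(txt)
  expect_equal(spectrumIds(back), c("s1", "s2"))
  for (id in c("s1", "s2")) {
    expect_equal(peakTable(back[[id]]), peakTable(lib[[id]]))
    expect_equal(nominalMw(back[[id]]), nominalMw(lib[[id]]))
    expect_equal(subclassLabel(back[[id]]), subclassLabel(lib[[id]]))
  }
  ## property: round trip over 5 generated spectra
  gen <- generateCohort(5, defaultClassSpecs()$xanthines, seed = 31)
  back2 <- parseMSP(writeMSP(gen))
  expect_equal(spectrumIds(back2), spectrumIds(gen))
  for (id in spectrumIds(gen))
    expect_equal(peakTable(back2[[id]]), peakTable(gen[[id]]), tolerance = 1e-12)

  expect_equal(writeMSP(SpectrumLibrary()), "")
})

test_that("normalizeToBasePeak scales to 100, is idempotent and scale-invariant", {
  s <- Spectrum(c(50, 100), c(10, 50))
  expect_equal(peakIntensity(normalizeToBasePeak(s)), c(20, 100))
  s2 <- Spectrum(c(10, 20, 30), c(1, 3, 4))
  expect_equal(peakIntensity(normalizeToBasePeak(s2)), c(25, 75, 100))
  n1 <- normalizeToBasePeak(s2)
  expect_equal(peakIntensity(normalizeToBasePeak(n1)), peakIntensity(n1))
  ## scale invariance over random spectra
  set.seed(4)
  for (i in 1:20) {
    p <- randomPeakList(8)
    k <- stats::runif(1, 0.01, 50)
    a <- normalizeToBasePeak(Spectrum(p$mz, p$intensity))
    b <- normalizeToBasePeak(Spectrum(p$mz, k * p$intensity))
    expect_equal(peakIntensity(a), peakIntensity(b))
  }
})

test_that("constructor rejects empty spectra and merges duplicate mz", {
  expect_error(Spectrum(numeric(), numeric()), "no peaks")
  expect_error(Spectrum(c(50, 100), c(0, 0)), "no peaks")
  expect_warning(s <- Spectrum(c(50, 50, 80), c(10, 20, 100)), "merged")
  expect_equal(peakTable(s), data.frame(mz = c(50, 80), intensity = c(30, 100)))
})

test_that("binNominal rounds half away from zero, merges and renormalizes", {
  s <- Spectrum(c(82.9, 83.1), c(40, 60))
  expect_equal(peakTable(binNominal(s)), data.frame(mz = 83, intensity = 100))

  ## 50.5 rounds up to 51; 49.6 rounds to 50
  s2 <- Spectrum(c(49.6, 50.5), c(10, 10))
  expect_equal(peakMz(binNominal(s2)), c(50, 51))
  expect_equal(peakIntensity(binNominal(s2)), c(100, 100))

  ## integer spectrum unchanged apart from renormalization
  s3 <- Spectrum(c(50, 100), c(30, 60))
  expect_equal(peakTable(binNominal(s3)),
               data.frame(mz = c(50, 100), intensity = c(50, 100)))

  ## intensity is conserved before renormalization: merged groups sum
  s4 <- Spectrum(c(99.7, 100.2, 100.4), c(10, 20, 30))
  b4 <- binNominal(s4)
  expect_equal(peakMz(b4), 100)
  expect_true(all(diff(peakMz(b4)) > 0))
})

test_that("validity flags spectra whose peaks exceed the stated MW", {
  s <- Spectrum(c(50, 130), c(10, 100), nominalMw = 126)
  expect_true(s@mwInconsistent)
  expect_error(SpectrumLibrary(list(
    Spectrum(50, 100, id = "a"), Spectrum(60, 100, id = "a"))),
    "duplicate")
})
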