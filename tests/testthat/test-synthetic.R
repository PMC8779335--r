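test_that("reference spectra are deterministic in the seed", {
  spec <- defaultClassSpecs()$guanines
  a <- generateReferenceSpectrum(spec, seed = 101)
  b <- generateReferenceSpectrum(spec, seed = 101)
  expect_equal(peakTable(a), peakTable(b))
  expect_equal(nominalMw(a), nominalMw(b))
  c <- generateReferenceSpectrum(spec, seed = 102)
  expect_false(isTRUE(all.equal(peakTable(a), peakTable(c))))
})

test_that("generator honours the molecular-ion and loss-profile settings", {
  base <- classSpec("x", c(150, 200), molionBaseProb = 1,
                    lossProfile = c(HCN = 1), hcnChainProb = 0)
  s <- generateReferenceSpectrum(base, seed = 3)
  expect_equal(molecularIonAbundance(s), 100)       # survival fixed at 100
  expect_true((nominalMw(s) - 27) %in% peakMz(s))   # certain HCN emission
  ## survival below 100: a fragment is the base peak and the molecular
  ## ion sits at its sampled survival percent exactly
  low <- classSpec("y", c(150, 200), molionBaseProb = 0,
                   molionSurvivalRange = c(30, 40))
  s2 <- generateReferenceSpectrum(low, seed = 4)
  expect_true(isNormalized <- abs(max(peakIntensity(s2)) - 100) < 1e-9)
  mi <- molecularIonAbundance(s2)
  expect_gte(mi, 30); expect_lte(mi, 40)
  expect_error(generateReferenceSpectrum(
    classSpec("z", c(45, 45), nFragmentsRange = c(30, 30)), seed = 1),
    "degenerate")
})

test_that("the identity perturbation returns the spectrum unchanged", {
  s <- generateReferenceSpectrum(defaultClassSpecs()$adenines, seed = 8)
  p <- perturbSpectrum(s, perturbationConfig(), seed = 5)
  expect_equal(peakTable(p), peakTable(s))
})

test_that("full dropout leaves only the molecular ion", {
  s <- generateReferenceSpectrum(defaultClassSpecs()$adenines, seed = 8)
  p <- perturbSpectrum(s, perturbationConfig(dropoutProb = 1), seed = 5)
  expect_equal(peakMz(p), nominalMw(s))
  expect_equal(peakIntensity(p), 100)
})

test_that("empirical dropout and extra-peak rates match configuration", {
  spec <- classSpec("x", c(170, 210), nFragmentsRange = c(20, 25),
                    molionBaseProb = 1, lossProfile = c(HCN = 0))
  ## dropout and extra peaks measured in separate cohorts so neither
  ## contaminates the other's count (an extra peak can land on a dropped
  ## fragment's m/z)
  cfgDrop <- perturbationConfig(dropoutProb = 0.35)
  cfgExtra <- perturbationConfig(extraPeakRate = 3)
  nDropped <- 0; nTotal <- 0; nExtra <- 0; nSpec <- 400
  for (i in seq_len(nSpec)) {
    s <- generateReferenceSpectrum(spec, seed = 5000 + i)
    p <- perturbSpectrum(s, cfgDrop, seed = 9000 + i)
    frag <- setdiff(peakMz(s), nominalMw(s))
    nDropped <- nDropped + sum(!frag %in% peakMz(p))
    nTotal <- nTotal + length(frag)
    pe <- perturbSpectrum(s, cfgExtra, seed = 12000 + i)
    nExtra <- nExtra + sum(!peakMz(pe) %in% peakMz(s))
  }
  pHat <- nDropped / nTotal
  se <- sqrt(0.35 * 0.65 / nTotal)
  expect_lt(abs(pHat - 0.35), 3 * se)
  lamHat <- nExtra / nSpec
  expect_lt(abs(lamHat - 3), 3 * sqrt(3 / nSpec))
})

test_that("evaluation sets are paired, reproducible and order-independent", {
  cfg <- perturbationConfig(dropoutProb = 0.1, intensityNoiseSigma = 0.1)
  ev <- generateEvaluationSet(6, cfg = cfg, decoysPerCompound = 2,
                              nFillers = 3, seed = 55)
  expect_equal(spectrumIds(ev$predicted), spectrumIds(ev$experimental))
  expect_equal(length(ev$library), 6 + 12 + 3)
  expect_true(all(ev$truth$trueId %in% spectrumIds(ev$library)))
  ## byte-identical MSP export on repeat generation
  ev2 <- generateEvaluationSet(6, cfg = cfg, decoysPerCompound = 2,
                               nFillers = 3, seed = 55)
  expect_identical(writeMSP(ev$library), writeMSP(ev2$library))
  ## a smaller run reproduces the same leading compounds (substreams)
  ev3 <- generateEvaluationSet(3, cfg = cfg, decoysPerCompound = 2,
                               nFillers = 3, seed = 55)
  expect_identical(writeMSP(ev3$experimental[1:3]),
                   writeMSP(ev$experimental[1:3]))
})

test_that("decoys share at least half of the target's fragment m/z", {
  ev <- generateEvaluationSet(5, decoysPerCompound = 3, nFillers = 0,
                              seed = 77)
  for (i in seq_len(5)) {
    e <- ev$experimental[[sprintf("C%03d", i)]]
    frag <- setdiff(peakMz(e), nominalMw(e))
    for (j in 1:3) {
      d <- ev$library[[sprintf("D%03d_%d", i, j)]]
      shared <- length(intersect(setdiff(peakMz(d), nominalMw(d)), frag))
      expect_gte(shared / length(frag), 0.5)
      expect_equal(nominalMw(d), nominalMw(e))
    }
  }
})

test_that("configured molecular-ion bias is recovered by classSummary", {
  specs <- lapply(defaultClassSpecs()[1:4], function(sp) {
    sp$molionBaseProb <- 0; sp$molionSurvivalRange <- c(30, 70); sp
  })
  cfg <- perturbationConfig(molionShiftMean = -15, molionShiftSd = 4)
  ev <- generateEvaluationSet(200, classSpecs = specs, cfg = cfg,
                              decoysPerCompound = 0, nFillers = 0, seed = 6)
  comps <- do.call(rbind, lapply(seq_len(200), function(i)
    compareMolecularIons(ev$predicted[[i]], ev$experimental[[i]])))
  cs <- classSummary(comps)
  expect_lt(abs(mean(comps$signedDiff) + 15), 1)
  expect_true(all(abs(cs$meanSignedDiff + 15) < 2))
})
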