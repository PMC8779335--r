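test_that("identical libraries give a perfect report", {
  lib <- generateCohort(5, defaultClassSpecs()$pyrimidines, seed = 61)
  rep <- runEvaluation(lib, lib, searchLibrary = lib)
  expect_equal(rep$records$wdot, rep(1000, 5))
  expect_equal(rep$records$cosine, rep(1000, 5))
  expect_equal(rep$records$rank, rep(1L, 5))
  expect_equal(rep$records$jaccard_t2, rep(1, 5))
  expect_equal(rep$records$molionDiff, rep(0, 5))
  expect_true(all(rep$records$band == "excellent"))
})

test_that("a single-pair report equals the individual operations' outputs", {
  e <- generateReferenceSpectrum(defaultClassSpecs()$xanthines, seed = 71,
                                 id = "m1")
  p <- perturbSpectrum(e, perturbationConfig(dropoutProb = 0.2,
                                             intensityNoiseSigma = 0.2),
                       seed = 72)
  rep <- runEvaluation(SpectrumLibrary(list(p)), SpectrumLibrary(list(e)))
  expect_equal(nrow(rep$records), 1)
  expect_equal(rep$records$wdot, wdotScore(p, e))
  expect_equal(rep$records$cosine, cosineScore(p, e))
  expect_equal(rep$records$band, scoreBand(wdotScore(p, e)))
  cc <- concordance(p, e, 2)
  expect_equal(rep$records$jaccard_t2, cc$jaccard)
  expect_equal(rep$records$pctMatched_t2, cc$pctMatched)
  mi <- compareMolecularIons(p, e)
  expect_equal(rep$records$molionDiff, mi$signedDiff)
  expect_equal(rep$records$nNeutralLosses, nrow(detectNeutralLosses(e)))
})

test_that("unpaired or disjoint libraries are rejected with the ids listed", {
  a <- SpectrumLibrary(list(Spectrum(100, 100, id = "x")))
  b <- SpectrumLibrary(list(Spectrum(100, 100, id = "y")))
  expect_error(runEvaluation(a, b), "no shared ids")
  c2 <- SpectrumLibrary(list(Spectrum(100, 100, id = "x"),
                             Spectrum(90, 100, id = "z")))
  expect_error(runEvaluation(a, c2), "unpaired ids: z")
})

test_that("scoreHistogram bins half-open with a closed top bin", {
  h <- scoreHistogram(c(100, 150, 950))
  expect_equal(sum(h$count), 3)
  expect_equal(h$count[h$low == 100], 2)
  expect_equal(h$count[h$low == 900], 1)
  ## boundary values: 200 falls in [200, 300); 1000 in the closed top bin
  h2 <- scoreHistogram(c(0, 200, 1000))
  expect_equal(h2$count[h2$low == 0], 1)
  expect_equal(h2$count[h2$low == 200], 1)
  expect_equal(h2$count[h2$low == 900], 1)
  expect_error(scoreHistogram(numeric()), "no scores")
  ## all perfect scores occupy only the top bin
  h3 <- scoreHistogram(rep(1000, 4))
  expect_equal(h3$count[h3$low == 900], 4)
  expect_equal(sum(h3$count), 4)
})

test_that("subclassBandTable means and counts match hand computation", {
  rec <- data.frame(subclass = c("a", "a", "b"),
                    wdot = c(900, 700, 300))
  tab <- subclassBandTable(rec)
  expect_equal(tab$meanScore[tab$subclass == "a"], 800)
  expect_equal(tab$n_excellent[tab$subclass == "a"], 1)
  expect_equal(tab$n_good[tab$subclass == "a"], 1)
  expect_equal(tab$n_poor[tab$subclass == "b"], 1)
  ## overall mean equals the mean of per-record scores
  expect_equal(sum(tab$n * tab$meanScore) / sum(tab$n),
               roundHalfUp(mean(rec$wdot)), tolerance = 0.5)
})

test_that("report aggregates are pure functions of the records", {
  cfg <- perturbationConfig(dropoutProb = 0.2, intensityNoiseSigma = 0.3,
                            extraPeakRate = 2)
  ev <- generateEvaluationSet(8, cfg = cfg, decoysPerCompound = 1,
                              nFillers = 2, seed = 91)
  rep <- runEvaluation(ev$predicted, ev$experimental, ev$library)
  expect_equal(rep$histogram, scoreHistogram(rep$records$wdot))
  expect_equal(rep$bandTable, subclassBandTable(rep$records))
  expect_equal(rep$topn$table,
               topnSummary(rep$records$rank, rep$records$wdot)$table)
  expect_equal(rep$molionByClass,
               classSummary(data.frame(subclass = rep$records$subclass,
                                       signedDiff = rep$records$molionDiff)))
  ## overall mean wdot to one decimal is the arithmetic mean of records
  expect_equal(roundHalfUp(mean(rep$records$wdot), 1),
               roundHalfUp(sum(rep$records$wdot) / nrow(rep$records), 1))
})
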