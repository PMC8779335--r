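## Synthetic spectrum generator.
##
## Emulates pairs of experimental/predicted unit-mass EI spectra of small
## heteroaromatics (purine/pyrimidine derivatives, nominal MW 110-210 u):
## a molecular ion with a variable survival fraction, fragments at the
## characteristic neutral-loss offsets, a body of further fragments with
## log-uniform intensities, and sub-threshold noise peaks. A seeded
## perturbation model turns a reference spectrum into its "predicted"
## counterpart, reproducing the error modes an in-silico predictor shows:
## missing fragment ions, spurious extra ions, intensity noise, and a
## biased molecular-ion abundance. Every generator is reproducible from
## (spec, config, seed), with per-item substreams so libraries are
## order-independent.

#' Structural-subclass generator specification
#'
#' Describes how reference spectra of one structural subclass are drawn:
#' the nominal-MW range, how many body fragments a spectrum carries, the
#' per-loss emission probabilities, and the molecular-ion survival
#' distribution (a point mass at 100 — molecular ion as base peak — mixed
#' with a uniform range).
#'
#' @param subclass label.
#' @param mwRange integer MW interval (u).
#' @param nFragmentsRange integer range for the number of body fragments
#'   (drawn uniformly).
#' @param lossProfile named numeric vector of emission probabilities for
#'   losses named as in [defaultLossTable()].
#' @param molionBaseProb probability that the molecular ion is the base
#'   peak (survival 100).
#' @param molionSurvivalRange uniform range for the survival percent when
#'   the molecular ion is not the base peak.
#' @param hcnChainProb probability of a second sequential HCN fragment
#'   (the M-54 pattern) given that the first HCN loss was emitted.
#' @return a list of class `ClassSpec`.
#' @seealso [defaultClassSpecs()] for the packaged twelve-subclass set.
#' @export
classSpec <- function(subclass, mwRange = c(110, 210),
                      nFragmentsRange = c(12, 18),
                      lossProfile = c(HCN = 0.5),
                      molionBaseProb = 0.6,
                      molionSurvivalRange = c(5, 95),
                      hcnChainProb = 0.3) {
  stopifnot(length(mwRange) == 2, mwRange[1] >= 40, mwRange[2] >= mwRange[1],
            all(lossProfile >= 0 & lossProfile <= 1),
            molionBaseProb >= 0, molionBaseProb <= 1,
            hcnChainProb >= 0, hcnChainProb <= 1)
  known <- defaultLossTable()$name
  if (!all(names(lossProfile) %in% known))
    stop("unknown loss names: ",
         paste(setdiff(names(lossProfile), known), collapse = ", "))
  structure(list(subclass = subclass, mwRange = mwRange,
                 nFragmentsRange = nFragmentsRange,
                 lossProfile = lossProfile,
                 molionBaseProb = molionBaseProb,
                 molionSurvivalRange = molionSurvivalRange,
                 hcnChainProb = hcnChainProb),
            class = "ClassSpec")
}

#' Default twelve-subclass generator set
#'
#' Generator specifications emulating the twelve structural subclasses of
#' purine and pyrimidine derivatives the evaluation is organized around.
#' Loss-emission probabilities encode the known chemistry: HCN loss in
#' most purine classes (0.89) and in pyrimidines (0.57) but not in
#' pyridopyrimidinedione or aza-purine derivatives (where the required
#' carbon is substituted); isocyanic/cyanic acid loss from
#' uracil/xanthine/lumazine-type rings; methyl isocyanate from
#' N-methylated rings; cyanamide from guanines and adenines; CO and water
#' predominantly from lumazines.
#'
#' @return named list of twelve [classSpec()] objects.
#' @export
defaultClassSpecs <- function() {
  specs <- list(
    classSpec("pyrimidines", c(110, 170),
              lossProfile = c(HCN = 0.57, HNCO_or_NCOH = 0.8, CH3NCO = 0.3)),
    classSpec("methylpurines", c(134, 190),
              lossProfile = c(HCN = 0.89, CH3NCO = 0.5, CO = 0.2)),
    classSpec("aminohydroxypurines", c(135, 190),
              lossProfile = c(HCN = 0.89, HNCO_or_NCOH = 0.4, CO = 0.2)),
    classSpec("adenines", c(135, 190),
              lossProfile = c(HCN = 0.89, CN2H2 = 0.5)),
    classSpec("xanthines", c(152, 196),
              lossProfile = c(HCN = 0.89, HNCO_or_NCOH = 0.9, CO = 0.5)),
    classSpec("hypoxanthines", c(136, 180),
              lossProfile = c(HCN = 0.89, HNCO_or_NCOH = 0.5)),
    classSpec("guanines", c(151, 195),
              lossProfile = c(HCN = 0.89, CN2H2 = 0.8)),
    classSpec("lumazines", c(162, 200),
              lossProfile = c(HCN = 0.89, HNCO_or_NCOH = 0.9, CO = 0.7,
                              H2O = 0.5)),
    classSpec("quinazolinediones", c(162, 200),
              lossProfile = c(HCN = 0.89, HNCO_or_NCOH = 0.6, CO = 0.5)),
    classSpec("remycins", c(175, 210),
              lossProfile = c(HCN = 0.89, HNCO_or_NCOH = 0.3, CO = 0.3)),
    classSpec("pyridopyrimidinediones", c(160, 195),
              lossProfile = c(HNCO_or_NCOH = 0.6, CO = 0.4)),
    classSpec("azapurines", c(121, 180),
              lossProfile = c(HNCO_or_NCOH = 0.3, CO = 0.2))
  )
  names(specs) <- vapply(specs, `[[`, "", "subclass")
  specs
}

#' Perturbation model configuration
#'
#' Parameters of the reference-to-predicted perturbation: per-fragment
#' dropout, Poisson-distributed spurious peaks, multiplicative log-normal
#' intensity noise, and an additive Gaussian shift of the molecular-ion
#' abundance. An all-zero configuration is the identity.
#'
#' @param dropoutProb probability in `[0, 1)` (or exactly 1 for the limit
#'   case) that a non-molecular-ion peak is removed.
#' @param extraPeakRate expected number of spurious peaks per spectrum
#'   (placed at unoccupied integer m/z in `[26, MW - 1]`).
#' @param intensityNoiseSigma standard deviation of the log-scale
#'   multiplicative intensity noise.
#' @param molionShiftMean,molionShiftSd mean and sd (percentage points) of
#'   the additive molecular-ion abundance shift; the shifted value is
#'   clipped to `[0.1, 100]` so the molecular ion stays present.
#' @param seed integer seed making the perturbation reproducible; `NULL`
#'   uses the ambient RNG stream.
#' @return a list of class `PerturbationConfig`.
#' @export
perturbationConfig <- function(dropoutProb = 0, extraPeakRate = 0,
                               intensityNoiseSigma = 0,
                               molionShiftMean = 0, molionShiftSd = 0,
                               seed = NULL) {
  stopifnot(dropoutProb >= 0, dropoutProb <= 1, extraPeakRate >= 0,
            intensityNoiseSigma >= 0, molionShiftSd >= 0)
  structure(list(dropoutProb = dropoutProb, extraPeakRate = extraPeakRate,
                 intensityNoiseSigma = intensityNoiseSigma,
                 molionShiftMean = molionShiftMean,
                 molionShiftSd = molionShiftSd, seed = seed),
            class = "PerturbationConfig")
}

## log-uniform fragment intensities on [2, 50]% of base peak: most body
## fragments are weak, a handful exceed the 20% strong-peak threshold
.fragIntensity <- function(n) exp(stats::runif(n, log(2), log(50)))

## sample() treats a length-1 vector as 1:x; avoid that trap
.sampleOne <- function(x) if (length(x) == 1L) x else sample(x, 1L)

#' Generate one synthetic reference spectrum
#'
#' Draws a spectrum from a [classSpec()]: nominal MW uniform in the class
#' range, molecular ion with the sampled survival intensity, fragments at
#' the emitted neutral-loss offsets (intensity uniform in 10-90), a body
#' of fragments at unoccupied m/z in `[26, MW - 15]` with log-uniform
#' intensities, and a few sub-threshold noise peaks (< 2). When the
#' sampled survival is below 100 the strongest fragment is pinned to
#' exactly 100, so the molecular-ion intensity equals the sampled survival
#' percent on the percent-of-base-peak scale.
#'
#' @param spec a [classSpec()] object.
#' @param seed integer seed; a fixed seed reproduces the spectrum exactly.
#' @param id,name identifier and compound name for the result.
#' @return a normalized [Spectrum-class].
#' @export
generateReferenceSpectrum <- function(spec, seed, id = name,
                                      name = paste0("syn-", seed)) {
  stopifnot(inherits(spec, "ClassSpec"))
  withLocalSeed(seed, {
    mw <- .sampleOne(spec$mwRange[1]:spec$mwRange[2])
    molion <- if (stats::runif(1) < spec$molionBaseProb) 100
              else stats::runif(1, spec$molionSurvivalRange[1],
                                spec$molionSurvivalRange[2])
    mz <- mw
    inten <- molion
    ## characteristic neutral-loss fragments
    tab <- defaultLossTable()
    for (nm in names(spec$lossProfile)) {
      if (stats::runif(1) < spec$lossProfile[[nm]]) {
        delta <- tab$delta[tab$name == nm]
        f <- mw - delta
        if (f >= 26 && !f %in% mz) {
          mz <- c(mz, f)
          inten <- c(inten, stats::runif(1, 10, 90))
        }
        if (nm == "HCN" && stats::runif(1) < spec$hcnChainProb) {
          f2 <- mw - 2L * delta
          if (f2 >= 26 && !f2 %in% mz) {
            mz <- c(mz, f2)
            inten <- c(inten, stats::runif(1, 5, 50))
          }
        }
      }
    }
    ## body fragments; loss-offset positions (and the M-54 HCN chain slot)
    ## are reserved so that loss prevalence is controlled by lossProfile
    ## alone, not by chance placements
    nFrag <- .sampleOne(spec$nFragmentsRange[1]:spec$nFragmentsRange[2])
    reserved <- c(mw - tab$delta, mw - 54L)
    pool <- setdiff(26:(mw - 15), c(mz, reserved))
    if (length(pool) < nFrag)
      stop("degenerate class spec: not enough free m/z positions below MW")
    body <- sample(pool, nFrag)
    mz <- c(mz, body)
    inten <- c(inten, .fragIntensity(nFrag))
    ## sub-threshold noise peaks
    nNoise <- stats::rpois(1, 4)
    pool <- setdiff(26:(mw - 1), mz)
    nNoise <- min(nNoise, length(pool))
    if (nNoise > 0) {
      mz <- c(mz, sample(pool, nNoise))
      inten <- c(inten, stats::runif(nNoise, 0.3, 1.9))
    }
    if (molion < 100) {
      frag <- which(mz != mw)
      inten[frag[which.max(inten[frag])]] <- 100
    }
    normalizeToBasePeak(
      Spectrum(mz = mz, intensity = inten, id = id, name = name,
               nominalMw = mw, subclass = spec$subclass))
  })
}

#' Perturb a reference spectrum into a "predicted" spectrum
#'
#' Applies the perturbation model of [perturbationConfig()], in order:
#' per-fragment dropout (the molecular ion is never dropped), spurious
#' extra peaks, multiplicative log-normal intensity noise, additive
#' molecular-ion shift with clipping to `[0.1, 100]`, and base-peak
#' renormalization.
#'
#' @param s a normalized [Spectrum-class].
#' @param cfg a [perturbationConfig()].
#' @param seed overrides `cfg$seed` when given.
#' @return the perturbed, normalized [Spectrum-class].
#' @export
perturbSpectrum <- function(s, cfg = perturbationConfig(), seed = cfg$seed) {
  stopifnot(is(s, "Spectrum"), inherits(cfg, "PerturbationConfig"))
  withLocalSeed(seed, {
    mz <- s@mz; inten <- s@intensity
    isMol <- mz == s@nominalMw
    keep <- isMol | stats::runif(length(mz)) >= cfg$dropoutProb
    if (!any(keep)) keep <- isMol  # degenerate: keep at least the mol ion
    mz <- mz[keep]; inten <- inten[keep]; isMol <- isMol[keep]
    if (!length(mz)) stop("perturbation removed all peaks")
    nExtra <- stats::rpois(1, cfg$extraPeakRate)
    pool <- setdiff(26:(s@nominalMw - 1), mz)
    nExtra <- min(nExtra, length(pool))
    if (nExtra > 0) {
      mz <- c(mz, sample(pool, nExtra))
      inten <- c(inten, stats::runif(nExtra, 2, 20))
      isMol <- c(isMol, rep(FALSE, nExtra))
    }
    if (cfg$intensityNoiseSigma > 0)
      inten <- inten * exp(stats::rnorm(length(inten), 0,
                                        cfg$intensityNoiseSigma))
    if (any(isMol) && (cfg$molionShiftMean != 0 || cfg$molionShiftSd != 0)) {
      shift <- stats::rnorm(1, cfg$molionShiftMean, cfg$molionShiftSd)
      inten[isMol] <- min(100, max(0.1, inten[isMol] + shift))
    }
    normalizeToBasePeak(
      Spectrum(mz = mz, intensity = inten, id = s@id, name = s@name,
               nominalMw = s@nominalMw, subclass = s@subclass))
  })
}

#' Generate a cohort of reference spectra from one class spec
#'
#' @param n number of spectra.
#' @param spec a [classSpec()].
#' @param seed master seed; spectrum `i` uses an order-independent
#'   substream.
#' @param idPrefix prefix for entry ids.
#' @return a [SpectrumLibrary-class].
#' @export
generateCohort <- function(n, spec, seed, idPrefix = spec$subclass) {
  entries <- lapply(seq_len(n), function(i)
    generateReferenceSpectrum(spec, substreamSeed(seed, i),
                              id = sprintf("%s-%04d", idPrefix, i)))
  SpectrumLibrary(entries, sourceLabel = paste0("synthetic ", spec$subclass))
}

#' Generate a full synthetic evaluation set
#'
#' Builds the three libraries a library-search evaluation needs:
#' `experimental` reference spectra (compounds assigned round-robin over
#' `classSpecs`), their `predicted` counterparts (the same compounds run
#' through [perturbSpectrum()] with `cfg`), and a decoy `library`
#' containing every experimental entry plus `decoysPerCompound`
#' structurally similar decoys per compound (same nominal MW, sharing at
#' least half of the fragment m/z values but with re-drawn intensities and
#' a few own fragments — emulating the rank ambiguity caused by
#' structurally similar compounds) and `nFillers` unrelated filler
#' spectra.
#'
#' @param nCompounds number of paired compounds (default 80).
#' @param classSpecs list of [classSpec()] objects (default the packaged
#'   twelve).
#' @param cfg a [perturbationConfig()] applied to make predicted spectra.
#' @param decoysPerCompound near-duplicate decoys per compound.
#' @param nFillers unrelated filler spectra in the search library.
#' @param seed master seed; all draws come from order-independent
#'   substreams.
#' @return list with elements `predicted`, `experimental`, `library`
#'   ([SpectrumLibrary-class] objects; predicted/experimental are paired
#'   by id) and `truth` (data.frame: `queryId`, `trueId`, `subclass`).
#' @export
generateEvaluationSet <- function(nCompounds = 80,
                                  classSpecs = defaultClassSpecs(),
                                  cfg = perturbationConfig(),
                                  decoysPerCompound = 5, nFillers = 20,
                                  seed = 1) {
  stopifnot(nCompounds >= 1)
  expE <- vector("list", nCompounds)
  predE <- vector("list", nCompounds)
  decoyE <- list()
  for (i in seq_len(nCompounds)) {
    spec <- classSpecs[[(i - 1L) %% length(classSpecs) + 1L]]
    base <- i * 16L
    id <- sprintf("C%03d", i)
    e <- generateReferenceSpectrum(spec, substreamSeed(seed, base), id = id,
                                   name = sprintf("synthetic %s %03d",
                                                  spec$subclass, i))
    expE[[i]] <- e
    predE[[i]] <- perturbSpectrum(e, cfg, seed = substreamSeed(seed, base + 1L))
    if (decoysPerCompound > 0)
      decoyE <- c(decoyE, lapply(seq_len(decoysPerCompound), function(j)
        .makeDecoy(e, substreamSeed(seed, base + 1L + j),
                   sprintf("D%03d_%d", i, j))))
  }
  fillE <- lapply(seq_len(nFillers), function(k) {
    spec <- classSpecs[[(k - 1L) %% length(classSpecs) + 1L]]
    generateReferenceSpectrum(spec, substreamSeed(seed, 7L + k * 16L),
                              id = sprintf("F%03d", k),
                              name = sprintf("filler %s %03d",
                                             spec$subclass, k))
  })
  list(
    predicted = SpectrumLibrary(predE, "synthetic predicted"),
    experimental = SpectrumLibrary(expE, "synthetic experimental"),
    library = SpectrumLibrary(c(expE, decoyE, fillE),
                              "synthetic search library"),
    truth = data.frame(
      queryId = vapply(predE, spectrumId, character(1)),
      trueId = vapply(expE, spectrumId, character(1)),
      subclass = vapply(expE, subclassLabel, character(1))
    )
  )
}

## A structurally similar decoy: same nominal MW (an isomer), molecular ion
## at its own survival intensity, ~60% of the target's fragment m/z kept
## (intensities re-drawn), plus a few fragments of its own.
.makeDecoy <- function(s, seed, id) {
  withLocalSeed(seed, {
    mw <- s@nominalMw
    frag <- s@mz[s@mz != mw]
    nKeep <- ceiling(0.6 * length(frag))
    keep <- sample(frag, nKeep)
    mz <- keep
    inten <- .fragIntensity(nKeep)
    nNew <- sample(3:8, 1)
    pool <- setdiff(26:(mw - 2), c(mz, mw))
    nNew <- min(nNew, length(pool))
    if (nNew > 0) {
      mz <- c(mz, sample(pool, nNew))
      inten <- c(inten, .fragIntensity(nNew))
    }
    molion <- if (stats::runif(1) < 0.5) 100 else stats::runif(1, 5, 95)
    mz <- c(mz, mw)
    inten <- c(inten, molion)
    if (molion < 100) inten[which.max(inten[-length(inten)])] <- 100
    normalizeToBasePeak(
      Spectrum(mz = mz, intensity = inten, id = id,
               name = paste0("decoy ", id), nominalMw = mw,
               subclass = s@subclass))
  })
}
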