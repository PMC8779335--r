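#' @import methods
NULL

#' Spectrum: a unit-mass EI mass spectrum
#'
#' An identified, class-labelled peak list. Peaks are stored as two parallel
#' vectors (`mz`, `intensity`) sorted by strictly increasing m/z. Intensities
#' are relative abundances; the canonical internal scale is percent of the
#' base peak (base peak = 100), which [normalizeToBasePeak()] enforces.
#' Nominal masses are integer u; fractional m/z values are tolerated until
#' [binNominal()] is applied.
#'
#' @slot id unique identifier within a library.
#' @slot name compound name (free text).
#' @slot nominalMw nominal molecular weight in u. Inferred from the largest
#'   observed m/z (and flagged via `mwInferred`) when the source record
#'   carries no MW field.
#' @slot subclass structural subclass label, `"unclassified"` when unknown.
#' @slot mz numeric vector of m/z values, strictly increasing, all >= 1.
#' @slot intensity numeric vector of relative abundances, all > 0.
#' @slot mwInferred `TRUE` when `nominalMw` was inferred rather than read.
#' @slot mwInconsistent `TRUE` when a peak above the stated nominal MW was
#'   observed; such spectra are kept but flagged.
#'
#' @seealso [Spectrum()] for the user constructor, [parseMSP()] for import.
#' @exportClass Spectrum
setClass("Spectrum",
  representation(
    id = "character",
    name = "character",
    nominalMw = "numeric",
    subclass = "character",
    mz = "numeric",
    intensity = "numeric",
    mwInferred = "logical",
    mwInconsistent = "logical"
  ),
  prototype(
    id = NA_character_, name = NA_character_, nominalMw = NA_real_,
    subclass = "unclassified", mz = numeric(), intensity = numeric(),
    mwInferred = FALSE, mwInconsistent = FALSE
  )
)

setValidity("Spectrum", function(object) {
  msg <- character()
  if (length(object@mz) != length(object@intensity))
    msg <- c(msg, "mz and intensity must have equal length")
  if (length(object@mz)) {
    if (any(object@mz < 1)) msg <- c(msg, "all mz must be >= 1")
    if (any(diff(object@mz) <= 0))
      msg <- c(msg, "mz must be strictly increasing (no duplicates)")
    if (any(!is.finite(object@intensity)) || any(object@intensity <= 0))
      msg <- c(msg, "all intensities must be finite and > 0")
  }
  if (!is.na(object@nominalMw) && length(object@mz) &&
      max(object@mz) > object@nominalMw + 1e-8 && !object@mwInconsistent)
    msg <- c(msg, "peak above nominalMw but spectrum not flagged mwInconsistent")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' Peaks are sorted by m/z; duplicate m/z values are merged by summing their
#' intensities (with a warning); zero-intensity peaks are dropped. When
#' `nominalMw` is missing it is inferred as the largest observed m/z and the
#' spectrum is flagged as inferred (the molecular ion is expected to be
#' present in 70 eV EI spectra of small aromatics).
#'
#' @param mz numeric vector of m/z values.
#' @param intensity numeric vector of relative abundances, same length.
#' @param id unique identifier; defaults to `name`.
#' @param name compound name.
#' @param nominalMw nominal molecular weight (u), or `NA` to infer.
#' @param subclass structural subclass label.
#' @return a [Spectrum-class] object.
#' @examples
#' s <- Spectrum(mz = c(43, 83, 126), intensity = c(5, 30, 100),
#'               name = "6-methyluracil-like", nominalMw = 126)
#' s
#' @export
Spectrum <- function(mz, intensity, id = name, name = "unnamed",
                     nominalMw = NA, subclass = "unclassified") {
  if (length(mz) != length(intensity))
    stop("mz and intensity must have equal length")
  keep <- intensity > 0
  mz <- as.numeric(mz[keep]); intensity <- as.numeric(intensity[keep])
  if (!length(mz)) stop("spectrum has no peaks with positive intensity")
  o <- order(mz)
  mz <- mz[o]; intensity <- intensity[o]
  if (anyDuplicated(mz)) {
    warning("duplicate mz values merged by summing intensities")
    intensity <- as.numeric(tapply(intensity, mz, sum))
    mz <- sort(unique(mz))
  }
  inferred <- FALSE
  if (is.na(nominalMw)) {
    nominalMw <- max(mz)
    inferred <- TRUE
  }
  inconsistent <- max(mz) > nominalMw + 1e-8
  new("Spectrum",
      id = as.character(id), name = as.character(name),
      nominalMw = as.numeric(nominalMw), subclass = as.character(subclass),
      mz = mz, intensity = intensity,
      mwInferred = inferred, mwInconsistent = inconsistent)
}

#' SpectrumLibrary: an ordered collection of spectra
#'
#' Holds the entries of a spectral library (a predicted set, an experimental
#' reference set, or a decoy search library). Entry ids must be unique.
#'
#' @slot entries list of [Spectrum-class] objects.
#' @slot sourceLabel free-text provenance label.
#' @seealso [SpectrumLibrary()], [parseMSP()], [writeMSP()].
#' @exportClass SpectrumLibrary
setClass("SpectrumLibrary",
  representation(entries = "list", sourceLabel = "character"),
  prototype(entries = list(), sourceLabel = "")
)

setValidity("SpectrumLibrary", function(object) {
  msg <- character()
  if (!all(vapply(object@entries, is, logical(1), "Spectrum")))
    msg <- c(msg, "all entries must be Spectrum objects")
  else {
    ids <- vapply(object@entries, function(s) s@id, character(1))
    if (anyDuplicated(ids))
      msg <- c(msg, paste("duplicate spectrum ids:",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SpectrumLibrary
#'
#' @param entries list of [Spectrum-class] objects with unique ids.
#' @param sourceLabel free-text label recording where the library came from.
#' @return a [SpectrumLibrary-class] object.
#' @export
SpectrumLibrary <- function(entries = list(), sourceLabel = "") {
  new("SpectrumLibrary", entries = entries,
      sourceLabel = as.character(sourceLabel))
}

#' SimilarityWeights: parameters of the mass-weighted dot product
#'
#' The per-peak weight is `intensity^intensityExponent * mz^massExponent`;
#' scores are cosines of (weighted) intensity vectors multiplied by
#' `scaleA`. The defaults (0.6, 3.0, 1000) are the classic mass-weighting
#' used by EI library search engines: the cubic mass term up-weights
#' high-m/z peaks, which carry the most structural information in unit-mass
#' spectra.
#'
#' @slot intensityExponent dimensionless exponent on intensity (default 0.6).
#' @slot massExponent dimensionless exponent on m/z (default 3.0).
#' @slot scaleA score scale factor (default 1000).
#' @seealso [similarityWeights()], [wdotScore()], [cosineScore()].
#' @exportClass SimilarityWeights
setClass("SimilarityWeights",
  representation(intensityExponent = "numeric", massExponent = "numeric",
                 scaleA = "numeric"),
  prototype(intensityExponent = 0.6, massExponent = 3.0, scaleA = 1000)
)

setValidity("SimilarityWeights", function(object) {
  if (length(object@intensityExponent) != 1 || object@intensityExponent <= 0 ||
      length(object@massExponent) != 1 || object@massExponent <= 0 ||
      length(object@scaleA) != 1 || object@scaleA <= 0)
    "intensityExponent, massExponent and scaleA must be scalar and > 0"
  else TRUE
})

#' Construct similarity weights
#'
#' @param intensityExponent exponent on intensity, default 0.6.
#' @param massExponent exponent on m/z, default 3.0.
#' @param scaleA score scale, default 1000.
#' @return a [SimilarityWeights-class] object.
#' @examples
#' similarityWeights()            # the standard EI search weighting
#' similarityWeights(1, 0, 1000)  # reduces wdot to the plain cosine
#' @export
similarityWeights <- function(intensityExponent = 0.6, massExponent = 3.0,
                              scaleA = 1000) {
  new("SimilarityWeights", intensityExponent = intensityExponent,
      massExponent = massExponent, scaleA = scaleA)
}
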