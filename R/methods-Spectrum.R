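#' Accessors for Spectrum objects
#'
#' Small accessor layer over the [Spectrum-class] slots: identifier, compound
#' name, nominal molecular weight, subclass label, and the peak list.
#'
#' @param x a [Spectrum-class] object.
#' @return `spectrumId`, `compoundName`, `subclassLabel`: character scalars.
#'   `nominalMw`: numeric scalar (u). `peakMz`, `peakIntensity`: numeric
#'   vectors. `peakTable`: a `data.frame` with columns `mz`, `intensity`.
#'   `nPeaks`: integer.
#' @name Spectrum-accessors
#' @aliases spectrumId compoundName nominalMw subclassLabel peakMz
#'   peakIntensity peakTable nPeaks
#' @examples
#' s <- Spectrum(c(83, 126), c(30, 100), name = "x", nominalMw = 126)
#' peakTable(s)
#' nominalMw(s)
NULL

#' @rdname Spectrum-accessors
setMethod("spectrumId", "Spectrum", function(x) x@id)

#' @rdname Spectrum-accessors
setMethod("compoundName", "Spectrum", function(x) x@name)

#' @rdname Spectrum-accessors
setMethod("nominalMw", "Spectrum", function(x) x@nominalMw)

#' @rdname Spectrum-accessors
setMethod("subclassLabel", "Spectrum", function(x) x@subclass)

#' @rdname Spectrum-accessors
setMethod("peakMz", "Spectrum", function(x) x@mz)

#' @rdname Spectrum-accessors
setMethod("peakIntensity", "Spectrum", function(x) x@intensity)

#' @rdname Spectrum-accessors
setMethod("peakTable", "Spectrum", function(x)
  data.frame(mz = x@mz, intensity = x@intensity))

#' @rdname Spectrum-accessors
setMethod("nPeaks", "Spectrum", function(x) length(x@mz))

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum '", object@id, "' (", object@name, ")\n", sep = "")
  cat("  nominal MW: ", object@nominalMw,
      if (object@mwInferred) " (inferred)" else "",
      if (object@mwInconsistent) " [inconsistent: peak above MW]" else "",
      "\n", sep = "")
  cat("  subclass:   ", object@subclass, "\n", sep = "")
  cat("  peaks:      ", length(object@mz), sep = "")
  if (length(object@mz)) {
    bp <- object@mz[which.max(object@intensity)]
    cat(", base peak at m/z ", bp, sep = "")
  }
  cat("\n")
})

## ---- normalization & binning ------------------------------------------

#' Normalize a spectrum to its base peak
#'
#' Rescales intensities so that the most intense peak (the base peak) is
#' exactly 100, the canonical percent-of-base-peak scale on which molecular
#' ion abundances are reported. Ratios between peaks are preserved; the
#' operation is idempotent and invariant to an overall rescaling of the
#' input.
#'
#' @param x a [Spectrum-class] object with at least one peak.
#' @return the rescaled [Spectrum-class].
#' @examples
#' s <- Spectrum(c(50, 100), c(10, 50))
#' peakIntensity(normalizeToBasePeak(s))  # 20 100
#' @rdname normalizeToBasePeak
#' @export
setMethod("normalizeToBasePeak", "Spectrum", function(x) {
  if (!length(x@mz)) stop("cannot normalize a spectrum with no peaks")
  x@intensity <- x@intensity / max(x@intensity) * 100
  validObject(x)
  x
})

#' Bin a spectrum to nominal (integer) mass
#'
#' Rounds each m/z to the nearest integer (halves away from zero, the
#' unit-mass convention), merges peaks landing on the same integer by
#' summing their intensities, and re-normalizes to base peak 100. Integer
#' spectra pass through unchanged apart from the renormalization.
#'
#' @param x a [Spectrum-class] object (m/z may be fractional).
#' @return a [Spectrum-class] with strictly increasing integer m/z.
#' @examples
#' s <- Spectrum(c(82.9, 83.1), c(40, 60))
#' peakTable(binNominal(s))  # single peak at 83, intensity 100
#' @rdname binNominal
#' @export
setMethod("binNominal", "Spectrum", function(x) {
  mz <- roundHalfUp(x@mz)
  inten <- as.numeric(tapply(x@intensity, mz, sum))
  mz <- sort(unique(mz))
  x@mz <- mz
  x@intensity <- inten
  if (!is.na(x@nominalMw)) x@nominalMw <- roundHalfUp(x@nominalMw)
  x@mwInconsistent <- !is.na(x@nominalMw) && max(mz) > x@nominalMw
  normalizeToBasePeak(x)
})

isNormalized <- function(s, tol = 1e-9) {
  length(s@intensity) > 0 && abs(max(s@intensity) - 100) < tol
}

isNominal <- function(s) all(isWholeNumber(s@mz))
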