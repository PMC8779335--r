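## Peak concordance: thresholded set comparison of fragment ions.
##
## Intensities do not enter the comparison beyond the abundance threshold;
## the Jaccard index is computed on m/z presence alone, which deliberately
## separates "was the fragmentation reaction predicted at all" from "was
## its abundance right".

#' Remove peaks below an abundance threshold
#'
#' Drops peaks whose relative intensity falls below `thresholdPct` percent
#' of the base peak. The base peak itself is always retained, so the result
#' is never empty for thresholds up to 100.
#'
#' @param s a [Spectrum-class] normalized to base peak 100.
#' @param thresholdPct threshold in percent of base peak (peaks with
#'   intensity `< thresholdPct` are removed). Must be `<= 100`.
#' @return the filtered [Spectrum-class].
#' @examples
#' s <- Spectrum(c(43, 83, 126), c(1.5, 30, 100))
#' peakMz(applyAbundanceThreshold(s, 2))   # 83 126
#' peakMz(applyAbundanceThreshold(s, 20))  # 83 126
#' @export
applyAbundanceThreshold <- function(s, thresholdPct) {
  stopifnot(is(s, "Spectrum"))
  if (!isNormalized(s))
    stop("spectrum must be normalized to base peak 100; see normalizeToBasePeak()")
  if (thresholdPct > 100)
    stop("threshold above 100% would leave no peaks")
  keep <- s@intensity >= thresholdPct | s@intensity == max(s@intensity)
  s@mz <- s@mz[keep]
  s@intensity <- s@intensity[keep]
  s
}

#' Matching, missing, and extra fragment ions between two spectra
#'
#' Applies the abundance threshold to both spectra, then compares their m/z
#' sets: `matched` ions occur in both, `missing` ions only in the
#' experimental spectrum, `extra` ions only in the predicted one. The
#' Jaccard index is `matched / (matched + missing + extra)` and
#' `pctMatched` is `100 * matched / (matched + missing)`, the percentage of
#' experimental ions that were predicted.
#'
#' @param predicted,experimental nominal-binned, normalized
#'   [Spectrum-class] objects.
#' @param thresholdPct abundance threshold in percent of base peak
#'   (default 2, the conventional floor below which trajectory statistics
#'   cannot resolve low-probability reactions).
#' @param includeMolIon if `FALSE`, the peak at each spectrum's nominal MW
#'   is excluded so only fragment ions are compared.
#' @return a one-row `data.frame`: `thresholdPct`, `matched`, `missing`,
#'   `extra`, `pctMatched`, `jaccard`.
#' @examples
#' p <- Spectrum(c(55, 83, 126), c(20, 50, 100))
#' e <- Spectrum(c(43, 83, 126), c(20, 50, 100))
#' concordance(p, e)  # matched 2, missing 1, extra 1, jaccard 0.5
#' @export
concordance <- function(predicted, experimental, thresholdPct = 2,
                        includeMolIon = TRUE) {
  p <- applyAbundanceThreshold(predicted, thresholdPct)
  e <- applyAbundanceThreshold(experimental, thresholdPct)
  pm <- p@mz; em <- e@mz
  if (!includeMolIon) {
    pm <- pm[pm != predicted@nominalMw]
    em <- em[em != experimental@nominalMw]
  }
  if (!length(em))
    stop("experimental spectrum has no peaks above the threshold")
  matched <- length(intersect(pm, em))
  missing <- length(setdiff(em, pm))
  extra <- length(setdiff(pm, em))
  uni <- matched + missing + extra
  data.frame(
    thresholdPct = thresholdPct,
    matched = matched, missing = missing, extra = extra,
    pctMatched = 100 * matched / (matched + missing),
    jaccard = if (uni > 0) matched / uni else NA_real_
  )
}

#' Concordance summary over paired libraries
#'
#' Runs [concordance()] for every id shared between a predicted and an
#' experimental library and aggregates per structural subclass (taken from
#' the experimental entry) and overall. Per-spectrum values enter the means
#' unweighted.
#'
#' @param predicted,experimental [SpectrumLibrary-class] objects paired by
#'   entry id.
#' @param thresholdPct abundance threshold in percent of base peak.
#' @param includeMolIon passed to [concordance()].
#' @return a list with elements `perPair` (one row per pair: id, subclass,
#'   counts, `pctMatched`, `jaccard`), `perClass` (per-subclass means), and
#'   `overall` (a one-row data.frame of overall means).
#' @export
concordanceSummary <- function(predicted, experimental, thresholdPct = 2,
                               includeMolIon = TRUE) {
  ids <- intersect(spectrumIds(predicted), spectrumIds(experimental))
  if (!length(ids)) stop("no shared ids between the two libraries")
  rows <- lapply(ids, function(id) {
    e <- experimental[[id]]
    cbind(data.frame(id = id, subclass = e@subclass),
          concordance(predicted[[id]], e, thresholdPct, includeMolIon))
  })
  perPair <- do.call(rbind, rows)
  agg <- function(d) data.frame(
    n = nrow(d),
    meanPctMatched = mean(d$pctMatched),
    meanExtra = mean(d$extra),
    meanJaccard = mean(d$jaccard)
  )
  perClass <- do.call(rbind, lapply(split(perPair, perPair$subclass), agg))
  perClass <- cbind(data.frame(subclass = rownames(perClass)), perClass)
  rownames(perClass) <- NULL
  list(perPair = perPair, perClass = perClass, overall = agg(perPair))
}

#' Spearman rank correlation
#'
#' Rank correlation with tie-averaged ranks and a two-sided p-value
#' (asymptotic t approximation, appropriate in the presence of ties).
#'
#' @param x,y numeric vectors of equal length >= 3; neither may be
#'   constant.
#' @return a list with elements `rho` and `pValue`.
#' @examples
#' spearmanCorrelation(1:5, c(2, 1, 4, 3, 5))
#' @export
spearmanCorrelation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("x and y must have equal length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("rank correlation is undefined for a constant vector")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), pValue = ct$p.value)
}
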