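## Spectral similarity on the 0-1000 scale.
##
## Both scores are cosines between intensity vectors laid out over the
## union of the two spectra's integer m/z values: the plain cosine uses raw
## intensities, the weighted dot product first transforms each peak by
## intensity^0.6 * mz^3, which shifts the emphasis to high-mass peaks where
## unit-mass EI spectra are most diagnostic.

#' Align two spectra over the union of their m/z values
#'
#' Builds paired intensity vectors with one entry per m/z occurring in
#' either spectrum (ascending), using intensity 0 where a spectrum has no
#' peak at that m/z. Matching is by exact integer m/z equality, so both
#' spectra must be nominal-binned (see [binNominal()]).
#'
#' @param a,b [Spectrum-class] objects with integer m/z.
#' @return a `data.frame` with columns `mz`, `intensityA`, `intensityB`.
#' @examples
#' a <- Spectrum(c(50, 100), c(100, 50)); b <- Spectrum(c(50, 100), c(50, 100))
#' alignUnion(a, b)
#' @export
alignUnion <- function(a, b) {
  stopifnot(is(a, "Spectrum"), is(b, "Spectrum"))
  if (!isNominal(a) || !isNominal(b))
    stop("spectra must be nominal-binned (integer m/z); see binNominal()")
  mz <- sort(union(a@mz, b@mz))
  ia <- ib <- numeric(length(mz))
  ia[match(a@mz, mz)] <- a@intensity
  ib[match(b@mz, mz)] <- b@intensity
  data.frame(mz = mz, intensityA = ia, intensityB = ib)
}

#' Per-peak mass weighting
#'
#' The weighted intensity of a peak is
#' `intensity^intensityExponent * mz^massExponent` (defaults 0.6 and 3.0).
#' Zero intensities (empty union slots) map to zero.
#'
#' @param intensity numeric vector of relative abundances (>= 0).
#' @param mz numeric vector of m/z values.
#' @param weights a [SimilarityWeights-class] object.
#' @return numeric vector of weighted intensities.
#' @examples
#' weightedIntensity(100, 100)  # 100^0.6 * 100^3
#' @export
weightedIntensity <- function(intensity, mz, weights = similarityWeights()) {
  ifelse(intensity > 0,
         intensity^weights@intensityExponent * mz^weights@massExponent,
         0)
}

## Cosine via the squared form: on identical vectors numerator and
## denominator are the same floating-point product, so the score is exactly
## scaleA; disjoint vectors give exactly 0. Rounding can push the ratio a
## hair above 1, hence the clamp.
.cosineOf <- function(x, y, scaleA) {
  sx <- sum(x * x); sy <- sum(y * y)
  if (sx == 0 || sy == 0) stop("cannot score a spectrum with no signal")
  d <- sum(x * y)
  sqrt(min(1, (d * d) / (sx * sy))) * scaleA
}

#' Cosine and weighted dot-product similarity scores
#'
#' `cosineScore` is the cosine of the two raw intensity vectors over the
#' m/z union, scaled to `0..scaleA` (1000 by default). `wdotScore` applies
#' the mass weighting of [weightedIntensity()] to each vector first. Both
#' are symmetric, invariant to overall intensity rescaling of either
#' spectrum, and reach `scaleA` exactly when the (weighted) vectors are
#' proportional — in particular on identical spectra. Spectra sharing no
#' m/z score 0.
#'
#' @param a,b non-empty [Spectrum-class] objects with integer m/z.
#' @param weights a [SimilarityWeights-class]; for `cosineScore` only
#'   `scaleA` is used.
#' @return numeric scalar in `[0, scaleA]` (full precision; display
#'   rounding is left to the caller).
#' @examples
#' a <- Spectrum(c(50, 100), c(100, 50)); b <- Spectrum(c(50, 100), c(50, 100))
#' cosineScore(a, b)  # 800
#' wdotScore(a, b)    # ~994.5: the mass weighting discounts low-mz disagreement
#' @export
cosineScore <- function(a, b, weights = similarityWeights()) {
  u <- alignUnion(a, b)
  .cosineOf(u$intensityA, u$intensityB, weights@scaleA)
}

#' @rdname cosineScore
#' @export
wdotScore <- function(a, b, weights = similarityWeights()) {
  u <- alignUnion(a, b)
  wa <- weightedIntensity(u$intensityA, u$mz, weights)
  wb <- weightedIntensity(u$intensityB, u$mz, weights)
  .cosineOf(wa, wb, weights@scaleA)
}

#' Quality band of a similarity score
#'
#' Maps scores to qualitative match bands. The default `"figure"` scheme
#' uses four bands with strict lower bounds: excellent (> 800), good
#' (> 600), fair (> 400), poor (<= 400). The alternative `"text"` scheme is
#' the coarser convention sometimes quoted for EI library searches: good
#' (> 850), moderate (> 600), poor (<= 600).
#'
#' @param score numeric vector of scores in `[0, scaleA]`.
#' @param scheme `"figure"` (default, four bands) or `"text"` (three bands).
#' @return character vector of band labels.
#' @examples
#' scoreBand(c(810, 500, 400))
#' scoreBand(c(860, 700), scheme = "text")
#' @export
scoreBand <- function(score, scheme = c("figure", "text")) {
  scheme <- match.arg(scheme)
  if (scheme == "figure")
    ifelse(score > 800, "excellent",
      ifelse(score > 600, "good",
        ifelse(score > 400, "fair", "poor")))
  else
    ifelse(score > 850, "good",
      ifelse(score > 600, "moderate", "poor"))
}

#' Pairwise similarity matrix between two libraries
#'
#' Computes `metric(rows[[i]], cols[[j]])` for every pair of entries. On a
#' self-comparison the diagonal equals `scaleA` and the matrix is the
#' transpose of the swapped-argument matrix (both metrics are symmetric).
#'
#' @param rows,cols non-empty [SpectrumLibrary-class] objects.
#' @param weights a [SimilarityWeights-class].
#' @param metric `"wdot"` (default) or `"cosine"`.
#' @return numeric matrix with row/column names set to the entry ids.
#' @export
similarityMatrix <- function(rows, cols, weights = similarityWeights(),
                             metric = c("wdot", "cosine")) {
  metric <- match.arg(metric)
  if (!length(rows@entries) || !length(cols@entries))
    stop("both libraries must be non-empty")
  f <- if (metric == "wdot") wdotScore else cosineScore
  rs <- spectra(rows); cs <- spectra(cols)
  out <- matrix(NA_real_, length(rs), length(cs),
                dimnames = list(names(rs), names(cs)))
  for (i in seq_along(rs)) for (j in seq_along(cs)) {
    out[i, j] <- tryCatch(f(rs[[i]], cs[[j]], weights),
      error = function(e) stop("scoring pair (", names(rs)[i], ", ",
                               names(cs)[j], "): ", conditionMessage(e)))
  }
  out
}
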