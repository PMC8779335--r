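## Neutral-loss annotation at the spectrum level.
##
## Purines and pyrimidines fragment through a small set of characteristic
## neutral losses: retro Diels-Alder ring opening ejects cyanic/isocyanic
## acid (both 43 u, indistinguishable at unit mass) or methyl isocyanate
## (57 u) from N-methylated rings; hydrogen cyanide (27 u, often twice in
## succession) leaves the imidazole ring; cyanamide (42 u) is the rDA
## product of guanines; carbon monoxide (28 u) and water (18 u) round out
## the common losses. Annotation here is purely arithmetical: a loss is
## called when a sufficiently intense peak sits at parent m/z minus delta.

#' Default neutral-loss table
#'
#' The characteristic neutral losses of purine/pyrimidine EI
#' fragmentation. The 43 u loss is reported under the single ambiguous
#' name `HNCO_or_NCOH` because unit-mass spectra cannot distinguish
#' isocyanic from cyanic acid. Extend by `rbind`-ing rows with `name` and
#' integer `delta` (u).
#'
#' @return a `data.frame` with columns `name`, `delta`.
#' @examples
#' defaultLossTable()
#' @export
defaultLossTable <- function() {
  data.frame(
    name = c("H2O", "HCN", "CO", "CN2H2", "HNCO_or_NCOH", "CH3NCO"),
    delta = c(18L, 27L, 28L, 42L, 43L, 57L)
  )
}

#' Detect neutral losses in a spectrum
#'
#' Generation-1 hits are peaks at `nominalMw - delta` for some loss in the
#' table; with `maxGeneration = 2`, each generation-1 fragment is treated
#' as a parent for one further loss (e.g. the M-54 pattern of two
#' successive HCN losses). Only peaks with intensity at or above
#' `minIntensity` are annotated, to avoid calling noise.
#'
#' @param s a normalized [Spectrum-class] with `nominalMw` set.
#' @param losses loss table as from [defaultLossTable()].
#' @param minIntensity minimum fragment intensity in percent of base peak
#'   (default 2, matching the concordance threshold).
#' @param maxGeneration 1 (losses from the molecular ion only) or 2
#'   (one further sequential loss).
#' @return a `data.frame` sorted by descending `fragmentMz` (possibly
#'   empty): `loss`, `delta`, `parentMz`, `fragmentMz`,
#'   `fragmentIntensity`, `generation`.
#' @examples
#' s <- Spectrum(c(83, 126), c(30, 100), nominalMw = 126)
#' detectNeutralLosses(s)  # HNCO_or_NCOH: 126 - 43 = 83
#' @export
detectNeutralLosses <- function(s, losses = defaultLossTable(),
                                minIntensity = 2, maxGeneration = 2) {
  stopifnot(is(s, "Spectrum"), maxGeneration %in% c(1, 2))
  if (is.na(s@nominalMw)) stop("spectrum has no nominal molecular weight")
  hitsFrom <- function(parentMz, gen) {
    frag <- parentMz - losses$delta
    idx <- match(frag, s@mz)
    ok <- !is.na(idx) & frag >= 1
    ok[ok] <- s@intensity[idx[ok]] >= minIntensity
    if (!any(ok)) return(NULL)
    data.frame(
      loss = losses$name[ok], delta = losses$delta[ok],
      parentMz = parentMz, fragmentMz = frag[ok],
      fragmentIntensity = s@intensity[idx[ok]], generation = gen
    )
  }
  g1 <- hitsFrom(s@nominalMw, 1L)
  out <- g1
  if (maxGeneration == 2 && !is.null(g1)) {
    g2 <- lapply(unique(g1$fragmentMz), hitsFrom, gen = 2L)
    out <- do.call(rbind, c(list(g1), g2))
  }
  if (is.null(out))
    return(data.frame(loss = character(), delta = integer(),
                      parentMz = numeric(), fragmentMz = numeric(),
                      fragmentIntensity = numeric(), generation = integer()))
  out <- out[order(-out$fragmentMz, out$generation, out$loss), ]
  rownames(out) <- NULL
  out
}

#' Prevalence of a neutral loss across a cohort
#'
#' Fraction of spectra exhibiting a given loss from the molecular ion
#' (generation 1), per structural subclass and overall. Invariant to
#' intensity rescaling of the spectra since only thresholded presence
#' enters.
#'
#' @param library a [SpectrumLibrary-class]; subclasses are read from the
#'   entries.
#' @param loss single-row loss definition (`name`, `delta`), e.g. one row
#'   of [defaultLossTable()].
#' @param minIntensity minimum fragment intensity (percent of base peak).
#' @return a `data.frame` with columns `subclass`, `n`, `nWithLoss`,
#'   `prevalence`; the last row (`subclass == "overall"`) pools all
#'   spectra.
#' @export
lossPrevalence <- function(library, loss, minIntensity = 2) {
  stopifnot(is(library, "SpectrumLibrary"), nrow(loss) == 1)
  has <- vapply(library@entries, function(s) {
    h <- detectNeutralLosses(s, losses = loss, minIntensity = minIntensity,
                             maxGeneration = 1)
    nrow(h) > 0
  }, logical(1))
  cls <- vapply(library@entries, function(s) s@subclass, character(1))
  agg <- function(sel, label) data.frame(
    subclass = label, n = sum(sel), nWithLoss = sum(has[sel]),
    prevalence = sum(has[sel]) / sum(sel)
  )
  out <- do.call(rbind, lapply(unique(cls), function(cl) agg(cls == cl, cl)))
  rbind(out, agg(rep(TRUE, length(has)), "overall"))
}
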