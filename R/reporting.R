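## Orchestration: run every evaluation stage over paired libraries and
## collect one record per compound plus recomputable aggregates.

#' Run the full spectrum-evaluation pipeline
#'
#' For every id shared by the predicted and experimental libraries this
#' computes the cosine and weighted dot-product similarity (with quality
#' band), the library-search rank of the true compound, peak concordance
#' at each requested abundance threshold, the molecular-ion comparison,
#' and the number of annotated neutral losses. Aggregates (top-N summary,
#' per-subclass molecular-ion summary, concordance summaries, subclass
#' band table, score histogram) are pure functions of the per-compound
#' records.
#'
#' @param predicted,experimental [SpectrumLibrary-class] objects paired by
#'   entry id; ids present in only one of them raise an error listing
#'   them.
#' @param searchLibrary [SpectrumLibrary-class] to rank queries against;
#'   must contain every experimental entry. `NULL` skips ranking.
#' @param weights a [SimilarityWeights-class].
#' @param thresholds abundance thresholds (percent of base peak) for the
#'   concordance stage.
#' @param windowPct accuracy window for molecular-ion classification.
#' @param searchDepth rank depth beyond which hits are out of range.
#' @param metric ranking metric, `"wdot"` or `"cosine"`.
#' @param bandScheme banding scheme for [scoreBand()].
#' @return a list of class `EvaluationReport`: `records` (one row per
#'   compound), `topn` (a `TopNSummary` or `NULL`), `molionByClass`,
#'   `concordance` (list of [concordanceSummary()] results, one per
#'   threshold), `bandTable`, `histogram`, and `config` (echo of the
#'   parameters).
#' @export
runEvaluation <- function(predicted, experimental, searchLibrary = NULL,
                          weights = similarityWeights(),
                          thresholds = c(2, 20), windowPct = 2,
                          searchDepth = 100, metric = "wdot",
                          bandScheme = "figure") {
  pid <- spectrumIds(predicted); eid <- spectrumIds(experimental)
  ids <- intersect(pid, eid)
  unpaired <- c(setdiff(pid, eid), setdiff(eid, pid))
  if (!length(ids))
    stop("no shared ids between predicted and experimental libraries")
  if (length(unpaired))
    stop("unpaired ids: ", paste(unpaired, collapse = ", "))
  recs <- lapply(ids, function(id) {
    p <- predicted[[id]]; e <- experimental[[id]]
    wd <- wdotScore(p, e, weights)
    rec <- data.frame(
      id = id, subclass = e@subclass, nominalMw = e@nominalMw,
      cosine = cosineScore(p, e, weights), wdot = wd,
      band = scoreBand(wd, bandScheme)
    )
    for (t in thresholds) {
      cc <- concordance(p, e, t)
      names(cc) <- paste0(names(cc), "_t", t)
      rec <- cbind(rec, cc[-1])
    }
    mi <- compareMolecularIons(p, e)
    rec$expMolion <- mi$expAbundance
    rec$predMolion <- mi$predAbundance
    rec$molionDiff <- mi$signedDiff
    rec$molionClass <- classifyPrediction(mi$signedDiff, windowPct)
    rec$nNeutralLosses <- nrow(detectNeutralLosses(e))
    rec
  })
  records <- do.call(rbind, recs)
  topn <- NULL
  if (!is.null(searchLibrary)) {
    ranks <- lapply(ids, function(id)
      rankQuery(predicted[[id]], searchLibrary, trueId = id,
                weights = weights, metric = metric,
                searchDepth = searchDepth))
    records$rank <- vapply(ranks, function(r) r$rank, integer(1))
    records$outOfRange <- vapply(ranks, function(r) r$outOfRange, logical(1))
    topn <- topnSummary(ranks, wdotScores = records$wdot)
  }
  conc <- lapply(thresholds, function(t)
    concordanceSummary(predicted, experimental, t))
  names(conc) <- paste0("t", thresholds)
  structure(list(
    records = records,
    topn = topn,
    molionByClass = classSummary(
      data.frame(subclass = records$subclass,
                 signedDiff = records$molionDiff), windowPct),
    concordance = conc,
    bandTable = subclassBandTable(records, scheme = bandScheme),
    histogram = scoreHistogram(records$wdot),
    config = list(weights = weights, thresholds = thresholds,
                  windowPct = windowPct, searchDepth = searchDepth,
                  metric = metric, bandScheme = bandScheme)
  ), class = "EvaluationReport")
}

#' @export
print.EvaluationReport <- function(x, ...) {
  cat("EvaluationReport:", nrow(x$records), "paired compounds\n")
  cat("  mean wdot:  ", roundHalfUp(mean(x$records$wdot), 1), "\n")
  cat("  mean cosine:", roundHalfUp(mean(x$records$cosine), 1), "\n")
  if (!is.null(x$topn)) {
    t1 <- x$topn$table
    cat("  top-1: ", t1$pct[t1$threshold == "1"], "%, top-10: ",
        t1$pct[t1$threshold == "10"], "%, out of range: ",
        x$topn$outOfRange, "\n", sep = "")
  }
  for (nm in names(x$concordance))
    cat("  mean % ions matched (", nm, "): ",
        roundHalfUp(x$concordance[[nm]]$overall$meanPctMatched, 1),
        "\n", sep = "")
  invisible(x)
}

#' Histogram of similarity scores
#'
#' Bins scores over the 0-1000 scale into half-open bins
#' `[low, low + width)`; the top bin is closed so a perfect score lands in
#' it. Counts sum to the number of scores.
#'
#' @param scores numeric vector of scores in `[0, 1000]` (or an
#'   `EvaluationReport`, whose wdot column is used).
#' @param binWidth bin width (default 100).
#' @param scaleA top of the score scale.
#' @return a `data.frame` with columns `low`, `high`, `count`.
#' @examples
#' scoreHistogram(c(100, 150, 950))
#' @export
scoreHistogram <- function(scores, binWidth = 100, scaleA = 1000) {
  if (inherits(scores, "EvaluationReport")) scores <- scores$records$wdot
  if (!length(scores)) stop("no scores to bin")
  lows <- seq(0, scaleA - binWidth, by = binWidth)
  counts <- vapply(lows, function(lo) {
    hi <- lo + binWidth
    if (hi >= scaleA) sum(scores >= lo & scores <= scaleA)
    else sum(scores >= lo & scores < hi)
  }, numeric(1))
  data.frame(low = lows, high = lows + binWidth, count = counts)
}

#' Per-subclass score means and band counts
#'
#' @param records `data.frame` with `subclass` and `wdot` columns (e.g.
#'   the `records` of an `EvaluationReport`, or any table of scores).
#' @param scheme banding scheme for [scoreBand()].
#' @return a `data.frame` with one row per subclass: `subclass`, `n`,
#'   `meanScore` (rounded to integer for display), plus one count column
#'   per band.
#' @export
subclassBandTable <- function(records, scheme = "figure") {
  if (inherits(records, "EvaluationReport")) records <- records$records
  stopifnot(all(c("subclass", "wdot") %in% names(records)))
  bandLevels <- if (scheme == "figure")
    c("excellent", "good", "fair", "poor")
  else c("good", "moderate", "poor")
  out <- lapply(unique(records$subclass), function(cl) {
    sc <- records$wdot[records$subclass == cl]
    bands <- factor(scoreBand(sc, scheme), levels = bandLevels)
    cnt <- as.list(table(bands))
    names(cnt) <- paste0("n_", names(cnt))
    cbind(data.frame(subclass = cl, n = length(sc),
                     meanScore = roundHalfUp(mean(sc))),
          as.data.frame(cnt))
  })
  do.call(rbind, out)
}
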