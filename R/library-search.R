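## Library search: rank a query's true compound among all library entries.
##
## Internally each library entry is reduced once to its (mz, weighted
## intensity, norm) triple; a pair's cosine then only needs the shared-mz
## dot product, because union slots where either spectrum is absent
## contribute zero to both the dot product and the norms. This is exactly
## the score wdotScore()/cosineScore() compute, just without rebuilding the
## union for every pair.

.weightedVectors <- function(lib, weights, metric) {
  lapply(spectra(lib), function(s) {
    w <- if (metric == "wdot")
      weightedIntensity(s@intensity, s@mz, weights) else s@intensity
    list(mz = s@mz, w = w, norm = sqrt(sum(w^2)))
  })
}

.pairScore <- function(qa, qb, scaleA) {
  hit <- match(qa$mz, qb$mz)
  ok <- !is.na(hit)
  if (!any(ok)) return(0)
  sum(qa$w[ok] * qb$w[hit[ok]]) / (qa$norm * qb$norm) * scaleA
}

#' Rank a query spectrum's true compound within a library
#'
#' Scores the query against every library entry, sorts descending, and
#' reports the rank of the true compound. Entries sharing a compound name
#' are treated as replicate spectra of one compound; by default the
#' compound's rank is that of its best-scoring replicate
#' (`replicateRule = "best"`), since an analyst accepts any replicate hit.
#' Ties share the worst tied position (conservative), so reported top-N
#' rates are lower bounds. Ranks beyond `searchDepth` are flagged out of
#' range.
#'
#' @param query a nominal-binned, normalized [Spectrum-class].
#' @param library a [SpectrumLibrary-class] to search.
#' @param trueId id of a library entry holding the query's true compound.
#' @param weights a [SimilarityWeights-class].
#' @param metric `"wdot"` (default) or `"cosine"`.
#' @param searchDepth ranks beyond this are reported as out of range
#'   (default 100, the depth beyond which library hits are not inspected
#'   in practice).
#' @param replicateRule `"best"` (rank of the best-scoring replicate
#'   entry) or `"strict"` (rank of the worst-scoring replicate).
#' @return a list of class `RankResult`: `queryId`, `trueId`, `rank`
#'   (integer, conservative tie position), `outOfRange` (logical),
#'   `score` (score of the ranking replicate), and `topHits` (data.frame
#'   of the `searchDepth` best ids and scores).
#' @export
rankQuery <- function(query, library, trueId,
                      weights = similarityWeights(),
                      metric = c("wdot", "cosine"),
                      searchDepth = 100, replicateRule = c("best", "strict")) {
  metric <- match.arg(metric)
  replicateRule <- match.arg(replicateRule)
  ids <- spectrumIds(library)
  if (!trueId %in% ids) stop("trueId '", trueId, "' not present in library")
  libVec <- .weightedVectors(library, weights, metric)
  qw <- if (metric == "wdot")
    weightedIntensity(query@intensity, query@mz, weights) else query@intensity
  qv <- list(mz = query@mz, w = qw, norm = sqrt(sum(qw^2)))
  if (qv$norm == 0) stop("query spectrum has no signal")
  scores <- vapply(libVec, .pairScore, numeric(1), qa = qv,
                   scaleA = weights@scaleA)
  trueName <- compoundName(library[[trueId]])
  names_ <- vapply(library@entries, function(s) s@name, character(1))
  replicate <- names_ == trueName
  ## conservative rank of one entry: entries scoring strictly better, plus
  ## all entries tied with it (itself included)
  consRank <- function(s) sum(scores > s) + sum(scores == s)
  repRanks <- vapply(scores[replicate], consRank, numeric(1))
  rank <- if (replicateRule == "best") min(repRanks) else max(repRanks)
  pick <- if (replicateRule == "best") which.max(scores[replicate])
          else which.min(scores[replicate])
  o <- order(scores, decreasing = TRUE)
  depth <- min(searchDepth, length(scores))
  structure(list(
    queryId = query@id, trueId = trueId,
    rank = as.integer(rank), outOfRange = rank > searchDepth,
    score = unname(scores[replicate][pick]),
    topHits = data.frame(id = ids[o[seq_len(depth)]],
                         score = unname(scores[o[seq_len(depth)]]))
  ), class = "RankResult")
}

#' @export
print.RankResult <- function(x, ...) {
  cat("RankResult: query '", x$queryId, "' vs true '", x$trueId, "'\n",
      sep = "")
  cat("  rank ", x$rank, if (x$outOfRange) " (out of range)", ", score ",
      roundHalfUp(x$score), "\n", sep = "")
  invisible(x)
}

#' Cumulative top-N identification summary
#'
#' Tabulates a set of [rankQuery()] results at the conventional cumulative
#' thresholds (top 1, 2, 3, 4, 5, 10, 100): the number of queries whose
#' true compound ranked within each threshold, the percentage of all
#' queries (rounded half up for display), and — when per-query weighted
#' dot-product scores are supplied — the mean score of the queries inside
#' each threshold. Queries ranked beyond the deepest threshold are counted
#' as out of range.
#'
#' @param ranks list of `RankResult` objects (or a bare integer vector of
#'   ranks).
#' @param wdotScores optional numeric vector, one score per query in the
#'   same order (typically the query-vs-own-reference Wdot).
#' @param thresholds integer vector of cumulative cut-offs.
#' @return a list of class `TopNSummary`: `table` (one row per threshold
#'   plus `outOfRange` and `total` rows with columns `count`, `pct`,
#'   `wdotAvg`), `total`, `outOfRange`.
#' @examples
#' topnSummary(c(1, 3, 200))$table
#' @export
topnSummary <- function(ranks, wdotScores = NULL,
                        thresholds = c(1, 2, 3, 4, 5, 10, 100)) {
  if (is.list(ranks) && all(vapply(ranks, inherits, logical(1), "RankResult")))
    ranks <- vapply(ranks, function(r) r$rank, numeric(1))
  ranks <- as.numeric(ranks)
  if (!length(ranks)) stop("no ranks supplied")
  if (!is.null(wdotScores) && length(wdotScores) != length(ranks))
    stop("wdotScores must have one value per rank")
  total <- length(ranks)
  depth <- max(thresholds)
  counts <- vapply(thresholds, function(t) sum(ranks <= t), numeric(1))
  oor <- sum(ranks > depth)
  avg <- function(sel) {
    if (is.null(wdotScores) || !any(sel)) NA_real_ else mean(wdotScores[sel])
  }
  wavg <- vapply(thresholds, function(t) avg(ranks <= t), numeric(1))
  tab <- data.frame(
    threshold = c(as.character(thresholds), "outOfRange", "total"),
    count = c(counts, oor, total),
    pct = roundHalfUp(100 * c(counts, oor, total) / total),
    wdotAvg = c(wavg, avg(ranks > depth), avg(rep(TRUE, total)))
  )
  structure(list(table = tab, total = total, outOfRange = oor),
            class = "TopNSummary")
}

#' @export
print.TopNSummary <- function(x, ...) {
  cat("Top-N identification summary (", x$total, " queries, ",
      x$outOfRange, " out of range)\n", sep = "")
  tab <- x$table
  tab$wdotAvg <- ifelse(is.na(tab$wdotAvg), NA, roundHalfUp(tab$wdotAvg))
  print(tab, row.names = FALSE)
  invisible(x)
}
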