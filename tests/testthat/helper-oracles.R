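## Independent brute-force oracles, deliberately written with plain loops
## and no reuse of package internals.

## Cosine of (optionally mass-weighted) intensity vectors over the m/z
## union, scaled by A. Weighting: intensity^m * mz^n, zero stays zero.
bruteForceScore <- function(mzA, iA, mzB, iB, weighted = TRUE,
                            m = 0.6, n = 3, A = 1000) {
  allMz <- sort(unique(c(mzA, mzB)))
  va <- vb <- numeric(length(allMz))
  for (k in seq_along(allMz)) {
    ia <- 0; ib <- 0
    for (j in seq_along(mzA)) if (mzA[j] == allMz[k]) ia <- iA[j]
    for (j in seq_along(mzB)) if (mzB[j] == allMz[k]) ib <- iB[j]
    if (weighted) {
      va[k] <- if (ia > 0) ia^m * allMz[k]^n else 0
      vb[k] <- if (ib > 0) ib^m * allMz[k]^n else 0
    } else {
      va[k] <- ia; vb[k] <- ib
    }
  }
  num <- 0; na <- 0; nb <- 0
  for (k in seq_along(allMz)) {
    num <- num + va[k] * vb[k]
    na <- na + va[k]^2
    nb <- nb + vb[k]^2
  }
  num / sqrt(na) / sqrt(nb) * A
}

## Explicit tie-averaged rank transform + Pearson product-moment formula.
bruteForceSpearman <- function(x, y) {
  tieRank <- function(v) {
    r <- numeric(length(v))
    for (i in seq_along(v)) {
      less <- sum(v < v[i])
      tied <- sum(v == v[i])
      r[i] <- less + (tied + 1) / 2
    }
    r
  }
  rx <- tieRank(x); ry <- tieRank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

## Random unit-mass spectrum with <= kMax peaks, as plain vectors.
randomPeakList <- function(kMax = 6) {
  k <- sample(1:kMax, 1)
  list(mz = sort(sample(26:300, k)),
       intensity = stats::runif(k, 0.5, 100))
}

asSpectrum <- function(p, id = "x", mw = NA) {
  Spectrum(mz = p$mz, intensity = p$intensity, id = id, nominalMw = mw)
}
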