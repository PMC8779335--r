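---
title: "Evaluating predicted EI mass spectra against reference libraries"
author: "eiSpectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating predicted EI mass spectra against reference libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eiSpectra)
```

## The problem

In silico methods can now predict 70 eV electron ionization (EI) mass
spectra directly from molecular structure, which makes it possible to
extend reference libraries to compounds for which no authentic standard
exists. Before such predicted spectra can be trusted for compound
identification, they have to be judged against experimental reference
spectra on several axes at once:

* **overall spectral similarity** — do the predicted intensities resemble
  the measured ones, especially in the high-m/z region that identifies a
  compound?
* **identification performance** — if the predicted spectrum is searched
  against a large reference library, does the correct structure come back
  as the top hit, or at least among the top few?
* **peak concordance** — which fragment ions were predicted at all, which
  experimental ions are missing, and how many spurious ions were invented?
* **molecular-ion accuracy** — is the survival fraction of the intact
  molecular ion (often the base peak for small aromatics) predicted at the
  right relative abundance?
* **fragmentation chemistry** — are the characteristic neutral losses of
  the compound class (for purines and pyrimidines: HCN, HNCO/NCOH,
  CH~3~NCO, CN~2~H~2~, CO, H~2~O) present in the predicted spectra?

`eiSpectra` implements this evaluation pipeline for unit-mass EI spectra,
together with a synthetic-spectrum generator that stands in for licensed
experimental libraries, so every stage is testable end to end with data
whose ground truth is known by construction.

## Data model

A `Spectrum` is a peak list `(m/z, intensity)` at nominal (integer) mass
with an identifier, compound name, nominal molecular weight (MW, in u)
and a structural-subclass label. The canonical intensity scale is percent
of the base peak: `normalizeToBasePeak()` makes the most intense peak
exactly 100, and all abundance thresholds and molecular-ion comparisons
are expressed on that scale. `binNominal()` collapses fractional m/z to
integers (halves round away from zero; co-landing peaks merge by summed
intensity). A `SpectrumLibrary` is an id-unique collection with MSP
import/export (`parseMSP()`, `writeMSP()`); both the space-separated and
`mz:intensity;` peak dialects found in public EI libraries are read, and
output is always space-separated with a deterministic field order so
libraries round-trip.

When a record carries no MW field the molecular weight is inferred as the
largest observed m/z and flagged — for the compound classes targeted
here the molecular ion is essentially always present, so this default is
safe, but the flag keeps the inference auditable.

## Similarity scores

Two spectra are compared over the union of their integer m/z values (a
slot missing in one spectrum contributes intensity 0). With intensity
vectors $I_A, I_B$ over that union,

$$\mathrm{Cos} = \frac{\sum I_A I_B}{\sqrt{\sum I_A^2\,\sum I_B^2}} \times A,$$

and the mass-weighted dot product applies the Stein–Scott style per-peak
weighting first,

$$W = I^{\,m}\, (m/z)^{\,n}, \qquad
\mathrm{Wdot} = \frac{\sum W_A W_B}{\sqrt{\sum W_A^2\,\sum W_B^2}} \times A,$$

with defaults $m = 0.6$, $n = 3.0$, $A = 1000$ (`similarityWeights()`).
The cubic mass term concentrates the score on high-m/z peaks — above all
the molecular ion — which is why Wdot usually outperforms the plain
cosine for small-molecule EI library search, and also why a mispredicted
molecular-ion abundance is punished heavily by Wdot but barely by the
cosine.

Numerically the cosine is evaluated in its squared form
$\smash{(\sum W_A W_B)^2 / (\sum W_A^2 \sum W_B^2)}$ and clamped at 1
before the square root, so identical spectra score exactly 1000, disjoint
spectra exactly 0, and rounding can never push a score above the scale.
Scores are carried at full precision; display rounding (integers for
scores, one decimal for averages) always rounds halves away from zero via
`roundHalfUp()`, matching how such tables are conventionally printed
(57.5 → 58, 73.75 → 74, 30.25 → 30.3 — round-half-to-even would get
these wrong).

Quality bands (`scoreBand()`): the default four-band scheme uses strict
lower bounds — excellent > 800, good > 600, fair > 400, poor otherwise.
A coarser three-band scheme (good > 850, moderate > 600, poor otherwise)
is available as `scheme = "text"`; the four-band scheme is the default
because it is the one used for class-level colouring of results.

## Peak concordance

`concordance()` reduces both spectra to their m/z sets above an abundance
threshold (default 2% of base peak, below which low-probability
fragmentation statistics are unreliable) and counts matched, missing
(experimental-only) and extra (predicted-only) ions. The threshold is
applied to **both** spectra, since spurious predicted ions are also
counted above a 2% cut. The Jaccard index
$J = \mathrm{matched}/(\mathrm{matched}+\mathrm{missing}+\mathrm{extra})$
deliberately ignores intensities: it isolates *whether a fragmentation
reaction was predicted at all* from whether its abundance was right. The
molecular ion is included in the sets by default (it is a spectral peak
like any other); `includeMolIon = FALSE` restricts the comparison to
fragments. Per-spectrum values enter cohort means unweighted — whether
size-weighting would be more appropriate is undecidable from the
reporting conventions this follows, and the unweighted mean is the
simpler, stated choice. `spearmanCorrelation()` (tie-averaged ranks,
two-sided asymptotic p) links concordance to the similarity scores.

## Library search

`rankQuery()` scores a query against every library entry and reports the
rank of the true compound. Two rules are deliberate, documented choices
(they are conventions, not facts about any particular search engine):

* **ties are conservative** — tied scores share the *worst* tied
  position, so reported top-N rates are lower bounds;
* **replicate entries** (same compound name) rank by their best-scoring
  replicate by default (`replicateRule = "best"`), since an analyst
  accepts any replicate hit; `"strict"` uses the worst replicate.

Ranks beyond `searchDepth` (default 100) are flagged out of range.
`topnSummary()` tabulates cumulative counts at 1, 2, 3, 4, 5, 10 and 100,
the corresponding percentages (rounded half up), and the mean Wdot of the
queries inside each threshold.

## Molecular-ion accuracy

`compareMolecularIons()` reports the signed difference (predicted minus
experimental, in percentage points of base-peak-relative abundance) of
the peak at the nominal MW. `classifyPrediction()` calls a prediction
accurate within a ±2 point window by default, with ±10 as the
conventional relaxed window; the window is interpreted in percentage
*points* on the percent-of-base-peak scale. `classSummary()` averages the
**absolute** differences within each structural subclass — the absolute
mean is the only definition that reproduces the packaged reference
table's printed class averages, and it is also robust to the one row of
that table whose printed sign is internally inconsistent
(`table2Fixture()` stores all 38 rows verbatim and flags that row
`sign_inconsistent`). The signed mean is reported alongside because it
estimates systematic bias, which the absolute mean cannot.

## Neutral-loss annotation

`detectNeutralLosses()` is deliberately simple: a loss is called when a
peak of at least `minIntensity` (default 2%, aligned with the
concordance threshold) sits at parent m/z minus the loss delta. The
default table covers the characteristic purine/pyrimidine losses —
HCN (27 u), CO (28 u), H~2~O (18 u), CN~2~H~2~ (42 u), HNCO/NCOH (43 u,
reported as one ambiguous loss because unit-mass spectra cannot separate
the isomers), CH~3~NCO (57 u). Generation 2 chains one further loss from
each first-generation fragment, which captures the M−54 signature of two
successive HCN losses; deeper cascades are chemically plausible but
unconstrained, so the depth is capped at 2. No mechanism is inferred —
annotation is mass arithmetic, nothing more.

## The synthetic-data generator

`generateReferenceSpectrum()` emulates a NIST-17-like experimental
spectrum of a small heteroaromatic; `perturbSpectrum()` degrades it into
its "predicted" counterpart; `generateEvaluationSet()` assembles paired
libraries plus a decoy search library. The defaults are the study
conditions the evaluation assumes, chosen once:

* **twelve structural subclasses** (`defaultClassSpecs()`) spanning
  nominal MW 110–210 u, the range of small purine/pyrimidine
  derivatives. Loss-emission probabilities encode the known chemistry:
  HCN in 89% of purine-class spectra and 57% of pyrimidines, none in
  pyridopyrimidinedione/aza-purine classes where the required carbon is
  substituted; isocyanic/cyanic acid from uracil-, xanthine- and
  lumazine-type rings; cyanamide from guanines and adenines; CO and
  water mainly from lumazines.
* **molecular ion**: base peak (survival 100) with probability 0.6 —
  close to the 61-of-80 fraction seen experimentally for these classes —
  otherwise uniform on 5–95%.
* **fragments**: 12–18 body fragments with log-uniform intensities on
  2–50% (most fragments weak, a handful above 20%), plus loss fragments
  at 10–90%, plus a Poisson(4) tail of sub-threshold noise peaks below
  2%. Body fragments avoid the loss-offset positions so that loss
  prevalence is controlled by the loss profile alone, and avoid m/z
  below 26 u, where EI fragments of these compounds are rare.
* **base-peak pinning**: when the sampled molecular-ion survival is
  below 100, the strongest fragment is pinned to exactly 100. This makes
  the molecular-ion intensity equal the sampled survival percent on the
  canonical scale, and it lets an additive molecular-ion shift pass
  through renormalization undistorted — which is what makes the
  bias-recovery check below exact rather than approximate.
* **perturbation** (`perturbationConfig()`): per-fragment dropout (the
  molecular ion is never dropped — experimentally it is present in all
  spectra of these classes), Poisson-rate spurious peaks at 2–20%
  intensity, multiplicative log-normal intensity noise, and an additive
  Gaussian molecular-ion shift clipped to [0.1, 100] so the molecular
  ion stays present.
* **decoys** (same nominal MW, 60% of the target's fragment m/z kept
  with re-drawn intensities, 3–8 own fragments, own molecular-ion
  survival) operationalize "structurally similar compound" as shared
  fragment sets, since spectra — not structures — cause the rank
  ambiguity a library search has to survive.
* **reproducibility**: every draw comes from a per-item substream of the
  master seed, so a library's entries do not depend on how many entries
  precede them and repeated generation is byte-identical down to the MSP
  export.

### What passing the synthetic checks does and does not show

The generator reproduces the *statistical* structure the evaluation
machinery assumes — controlled dropout/extra-ion rates, a tunable
molecular-ion bias, class-specific loss prevalence, decoy-induced rank
ambiguity — so the checks demonstrate that each statistic recovers the
parameter that generated the data (dropout 0.35 yields ≈ 65% matched
ions; a −15-point molecular-ion bias is recovered within 2 points at
n = 500; emission probability 0.89 is recovered within binomial error).
They do **not** show that any particular prediction method achieves such
numbers on real spectra: real prediction errors are structured by
chemistry, not i.i.d. In particular, real missingness is
intensity-dependent (weak experimental ions are the hard ones to
predict), which is why raising the abundance threshold from 2% to 20%
raises the observed matched fraction strongly on real data. The uniform
dropout model reproduces the direction of that effect only weakly
(through the never-dropped molecular ion's larger weight in the smaller
high-threshold set), and under multiplicative intensity noise the effect
can even invert, because noise pushes borderline peaks across the
threshold. This is a known, accepted limitation of the i.i.d. error
model rather than a defect of the concordance statistics.

### Problem sizes used by the packaged checks

The test-suite and the acceptance script exercise the pipeline at sizes
chosen to give comfortable statistical margins at interactive runtimes:
200 pairs for the dropout-regime concordance check (binomial SE ≈ 1
point), 80 queries against a 500-entry decoy library (the canonical
cohort-versus-library shape) for rank recovery, 500 pairs for
molecular-ion bias recovery, 100 spectra per class for loss prevalence,
and 1000 random ≤ 6-peak pairs for the brute-force score oracle.

## Degenerate inputs and edge rules

* Empty spectra are unconstructable; all-zero intensity vectors are
  rejected at construction.
* Duplicate m/z within a record merge by summation with a warning (the
  same rule `binNominal()` applies).
* A peak above the stated MW flags the spectrum `mwInconsistent` rather
  than failing: such records occur in real libraries and remain usable.
* Abundance thresholds always retain the base peak, so thresholding
  cannot empty a spectrum (thresholds above 100 are errors).
* Scoring an empty-signal vector, rank-searching for an absent id, and
  correlating a constant vector are errors, not NAs.
* `sample()`-style length-1 traps in the generator are guarded, so
  degenerate MW ranges behave.

## Known limitations

* Matching is exact integer m/z after nominal binning; there is no
  tolerance window, no isotope (M+1) handling and no
  precursor-shift/hybrid matching.
* The Jaccard machinery offers no intensity-weighted variant by design.
* The i.i.d. perturbation model (see above) understates
  intensity-dependent missingness.
* MW is metadata; no formula or exact-mass computation is attempted.
* The subclass label is free text carried through the pipeline; nothing
  validates it against actual structure.
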