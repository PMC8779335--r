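Package: eiSpectra
Title: Evaluation of Predicted Electron Ionization Mass Spectra Against
    Reference Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for judging computationally predicted 70 eV electron
    ionization (EI) mass spectra against experimental reference spectra at
    unit mass resolution. Provides NIST-style MSP import/export, base-peak
    normalization and nominal-mass binning, cosine and mass-weighted
    dot-product similarity scores on the 0-1000 scale, peak-concordance
    analysis via the Jaccard index at configurable abundance thresholds,
    library-search rank statistics with cumulative top-N summaries,
    molecular-ion abundance accuracy classification, neutral-loss
    annotation for purine and pyrimidine fragmentation chemistry, and a
    seeded synthetic-spectrum generator with decoy libraries so that the
    whole evaluation pipeline is testable without licensed reference data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'methods-Spectrum.R'
    'methods-SpectrumLibrary.R'
    'msp.R'
    'similarity.R'
    'concordance.R'
    'library-search.R'
    'molecular-ion.R'
    'neutral-loss.R'
    'synthetic.R'
    'reporting.R'
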