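#' @rdname Spectrum-accessors
#' @export
setGeneric("spectrumId", function(x) standardGeneric("spectrumId"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("compoundName", function(x) standardGeneric("compoundName"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("nominalMw", function(x) standardGeneric("nominalMw"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("subclassLabel", function(x) standardGeneric("subclassLabel"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("peakMz", function(x) standardGeneric("peakMz"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("peakIntensity", function(x) standardGeneric("peakIntensity"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("peakTable", function(x) standardGeneric("peakTable"))

#' @rdname Spectrum-accessors
#' @export
setGeneric("nPeaks", function(x) standardGeneric("nPeaks"))

#' @rdname normalizeToBasePeak
#' @export
setGeneric("normalizeToBasePeak", function(x) standardGeneric("normalizeToBasePeak"))

#' @rdname binNominal
#' @export
setGeneric("binNominal", function(x) standardGeneric("binNominal"))

#' @rdname SpectrumLibrary-accessors
#' @export
setGeneric("spectra", function(x) standardGeneric("spectra"))

#' @rdname SpectrumLibrary-accessors
#' @export
setGeneric("spectrumIds", function(x) standardGeneric("spectrumIds"))

#' @rdname SpectrumLibrary-accessors
#' @export
setGeneric("sourceLabel", function(x) standardGeneric("sourceLabel"))
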