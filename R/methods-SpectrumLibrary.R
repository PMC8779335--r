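#' Accessors for SpectrumLibrary objects
#'
#' @param x a [SpectrumLibrary-class] object.
#' @return `spectra`: the list of [Spectrum-class] entries, named by id.
#'   `spectrumIds`: character vector of entry ids. `sourceLabel`: character
#'   scalar.
#' @name SpectrumLibrary-accessors
#' @aliases spectra spectrumIds sourceLabel
NULL

#' @rdname SpectrumLibrary-accessors
setMethod("spectra", "SpectrumLibrary", function(x) {
  out <- x@entries
  names(out) <- vapply(out, function(s) s@id, character(1))
  out
})

#' @rdname SpectrumLibrary-accessors
setMethod("spectrumIds", "SpectrumLibrary", function(x)
  vapply(x@entries, function(s) s@id, character(1)))

#' @rdname SpectrumLibrary-accessors
setMethod("sourceLabel", "SpectrumLibrary", function(x) x@sourceLabel)

#' @param x a [SpectrumLibrary-class] object.
#' @rdname SpectrumLibrary-accessors
#' @export
setMethod("length", "SpectrumLibrary", function(x) length(x@entries))

#' @param i index or id of the entry to extract.
#' @rdname SpectrumLibrary-accessors
#' @export
setMethod("[[", "SpectrumLibrary", function(x, i) {
  if (is.character(i)) {
    hit <- match(i, spectrumIds(x))
    if (is.na(hit)) stop("no spectrum with id '", i, "'")
    i <- hit
  }
  x@entries[[i]]
})

#' @param j,drop,... ignored; present for generic compatibility.
#' @rdname SpectrumLibrary-accessors
#' @export
setMethod("[", "SpectrumLibrary", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, spectrumIds(x))
  initialize(x, entries = x@entries[i])
})

setMethod("show", "SpectrumLibrary", function(object) {
  cat("SpectrumLibrary with ", length(object@entries), " spectra",
      if (nzchar(object@sourceLabel))
        paste0(" [", object@sourceLabel, "]"), "\n", sep = "")
  n <- min(3L, length(object@entries))
  for (i in seq_len(n)) {
    s <- object@entries[[i]]
    cat("  ", s@id, ": MW ", s@nominalMw, ", ", length(s@mz), " peaks (",
        s@subclass, ")\n", sep = "")
  }
  if (length(object@entries) > n) cat("  ...\n")
})

## Apply a function over entries, returning a plain list named by id.
libApply <- function(lib, f, ...) {
  out <- lapply(lib@entries, f, ...)
  names(out) <- spectrumIds(lib)
  out
}
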