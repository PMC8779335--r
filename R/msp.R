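## NIST-style MSP text format.
##
## Records: "Name:" then metadata lines, "Num Peaks:", then peak lines, and
## a blank line (or end of text) terminating the record. Two peak encodings
## circulate in public EI libraries and both are accepted on input:
##   "mz intensity"  (whitespace separated, one or more pairs per line)
##   "mz:intensity;" (colon pairs, semicolon separated)
## Output is always space-separated, one peak per line.

#' Parse MSP-format text into a spectrum library
#'
#' Parses zero or more NIST-style MSP records. Recognized header fields are
#' `Name:`, `ID:` (optional; defaults to the name), `MW:` / `ExactMass:`,
#' `Comment:`/`Comments:` (a `subclass=<label>` token inside the comment is
#' picked up as the structural subclass), and `Num Peaks:`. Unknown header
#' lines are ignored. Peaks are sorted by m/z; a missing MW is inferred as
#' the largest observed m/z and flagged on the resulting [Spectrum-class].
#'
#' @param text character: MSP content, either a single string (possibly with
#'   embedded newlines) or a vector of lines.
#' @param sourceLabel label stored on the returned library.
#' @return a [SpectrumLibrary-class].
#' @section Errors: a malformed peak line aborts with a message naming the
#'   record and line number; a `Num Peaks` count that does not match the
#'   number of parsed peaks is a validation error.
#' @seealso [writeMSP()] for the inverse, [readMSP()] for files.
#' @examples
#' txt <- "Name: demo\nMW: 126\nNum Peaks: 2\n83 30\n126 100\n"
#' lib <- parseMSP(txt)
#' peakTable(lib[["demo"]])
#' @export
parseMSP <- function(text, sourceLabel = "msp") {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1L]]
           else as.character(text)
  lines <- sub("\r$", "", lines)
  entries <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!grepl("^\\s*Name\\s*:", lines[i], ignore.case = TRUE)) {
      if (grepl("^\\s*$", lines[i])) { i <- i + 1L; next }
      stop("expected 'Name:' at line ", i, ", got: ", lines[i])
    }
    rec <- list(name = trimws(sub("^\\s*Name\\s*:", "", lines[i],
                                  ignore.case = TRUE)),
                id = NA_character_, mw = NA_real_,
                subclass = "unclassified", numPeaks = NA_integer_)
    i <- i + 1L
    ## header lines until Num Peaks:
    while (i <= n && !grepl("^\\s*Num\\s*Peaks\\s*:", lines[i],
                            ignore.case = TRUE)) {
      ln <- lines[i]
      if (grepl("^\\s*$", ln)) {
        stop("record '", rec$name, "' has no 'Num Peaks:' line")
      } else if (grepl("^\\s*ID\\s*:", ln, ignore.case = TRUE)) {
        rec$id <- trimws(sub("^\\s*ID\\s*:", "", ln, ignore.case = TRUE))
      } else if (grepl("^\\s*MW\\s*:", ln, ignore.case = TRUE)) {
        rec$mw <- suppressWarnings(
          as.numeric(trimws(sub("^\\s*MW\\s*:", "", ln, ignore.case = TRUE))))
      } else if (grepl("^\\s*Comments?\\s*:", ln, ignore.case = TRUE)) {
        cm <- trimws(sub("^\\s*Comments?\\s*:", "", ln, ignore.case = TRUE))
        m <- regmatches(cm, regexpr("subclass=[^;,[:space:]]+", cm))
        if (length(m)) rec$subclass <- sub("^subclass=", "", m)
      }
      ## other metadata (Formula:, CAS#:, Synon: ...) is ignored
      i <- i + 1L
    }
    if (i > n) stop("record '", rec$name, "' has no 'Num Peaks:' line")
    rec$numPeaks <- suppressWarnings(as.integer(
      trimws(sub("^\\s*Num\\s*Peaks\\s*:", "", lines[i], ignore.case = TRUE))))
    if (is.na(rec$numPeaks))
      stop("record '", rec$name, "': unreadable 'Num Peaks' at line ", i)
    i <- i + 1L
    ## peak lines until blank line, next Name:, or end
    mz <- numeric(); inten <- numeric()
    while (i <= n && !grepl("^\\s*$", lines[i]) &&
           !grepl("^\\s*Name\\s*:", lines[i], ignore.case = TRUE)) {
      pk <- .parsePeakLine(lines[i], rec$name, i)
      mz <- c(mz, pk$mz); inten <- c(inten, pk$intensity)
      i <- i + 1L
    }
    if (length(mz) != rec$numPeaks)
      stop("record '", rec$name, "': 'Num Peaks: ", rec$numPeaks,
           "' but ", length(mz), " peaks listed")
    if (is.na(rec$id)) rec$id <- rec$name
    entries[[length(entries) + 1L]] <-
      Spectrum(mz = mz, intensity = inten, id = rec$id, name = rec$name,
               nominalMw = rec$mw, subclass = rec$subclass)
  }
  SpectrumLibrary(entries = entries, sourceLabel = sourceLabel)
}

.parsePeakLine <- function(ln, recName, lineNo) {
  txt <- trimws(ln)
  ## colon dialect: "mz:intensity; mz:intensity;"
  if (grepl(":", txt, fixed = TRUE)) {
    parts <- strsplit(txt, ";", fixed = TRUE)[[1L]]
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    kv <- strsplit(parts, ":", fixed = TRUE)
    if (!length(kv) || any(lengths(kv) != 2L))
      stop("record '", recName, "': malformed peak line ", lineNo, ": ", ln)
    mz <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 1L)))
    inten <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2L)))
  } else {
    toks <- strsplit(gsub("[;,]", " ", txt), "[[:space:]]+")[[1L]]
    toks <- toks[nzchar(toks)]
    if (!length(toks) || length(toks) %% 2L != 0L)
      stop("record '", recName, "': malformed peak line ", lineNo, ": ", ln)
    vals <- suppressWarnings(as.numeric(toks))
    mz <- vals[seq(1L, length(vals), by = 2L)]
    inten <- vals[seq(2L, length(vals), by = 2L)]
  }
  if (anyNA(mz) || anyNA(inten))
    stop("record '", recName, "': malformed peak line ", lineNo, ": ", ln)
  list(mz = mz, intensity = inten)
}

#' Serialize a spectrum library to MSP text
#'
#' Writes NIST-style records with a deterministic field order (`Name`, `ID`
#' when it differs from the name, `MW`, `Comment` carrying the subclass tag,
#' `Num Peaks`, then one space-separated peak per line in ascending m/z),
#' so that [parseMSP()] round-trips to an equal library. An empty library
#' yields an empty string.
#'
#' @param library a [SpectrumLibrary-class].
#' @param scale999 if `TRUE`, intensities are exported on the 0-999 integer
#'   scale used by some library formats instead of percent of base peak.
#' @return a single character string of MSP text.
#' @examples
#' s <- Spectrum(c(43, 126), c(10, 100), name = "demo", nominalMw = 126)
#' cat(writeMSP(SpectrumLibrary(list(s))))
#' @export
writeMSP <- function(library, scale999 = FALSE) {
  stopifnot(is(library, "SpectrumLibrary"))
  recs <- vapply(library@entries, function(s) {
    inten <- s@intensity
    if (scale999) inten <- roundHalfUp(inten / max(inten) * 999)
    hdr <- c(
      paste0("Name: ", s@name),
      if (!identical(s@id, s@name)) paste0("ID: ", s@id),
      paste0("MW: ", format(s@nominalMw, scientific = FALSE)),
      paste0("Comment: subclass=", s@subclass),
      paste0("Num Peaks: ", length(s@mz))
    )
    pks <- paste(format(s@mz, trim = TRUE, scientific = FALSE),
                 format(inten, trim = TRUE, scientific = FALSE, digits = 15))
    paste(c(hdr, pks, ""), collapse = "\n")
  }, character(1))
  paste(recs, collapse = "\n")
}

#' Read / write MSP files
#'
#' Thin file wrappers around [parseMSP()] and [writeMSP()].
#'
#' @param path file path.
#' @param ... passed on to [parseMSP()] / [writeMSP()].
#' @return `readMSP`: a [SpectrumLibrary-class]. `writeMSPFile`: `path`,
#'   invisibly.
#' @export
readMSP <- function(path, ...) parseMSP(readLines(path, warn = FALSE),
                                        sourceLabel = basename(path), ...)

#' @param library a [SpectrumLibrary-class] to write.
#' @rdname readMSP
#' @export
writeMSPFile <- function(library, path, ...) {
  writeLines(writeMSP(library, ...), path)
  invisible(path)
}
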