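#' Round half away from zero
#'
#' Classic "commercial" rounding: exact halves move away from zero, unlike
#' [base::round()] which rounds half to even. Used wherever displayed
#' percentages and one-decimal class averages are produced, so that 57.5
#' rounds to 58 and 30.25 to 30.3.
#'
#' @param x numeric vector.
#' @param digits integer, number of decimal places to keep.
#' @return numeric vector rounded to `digits` decimals.
#' @examples
#' roundHalfUp(c(57.5, 73.75, -0.5), 0)
#' roundHalfUp(30.25, 1)
#' @export
roundHalfUp <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

## Evaluate expr with a local, reproducible RNG state; the caller's
## .Random.seed is untouched. seed = NULL leaves the RNG alone.
withLocalSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Derive a per-item substream seed from a master seed so that libraries are
## order-independent: item i always sees the same stream regardless of how
## many items precede it. Kept below 2^31 (R integers are 32-bit).
substreamSeed <- function(seed, i) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + as.double(i) * 16807) %%
               2147483647)
}

isWholeNumber <- function(x, tol = 1e-8) {
  abs(x - round(x)) < tol
}
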