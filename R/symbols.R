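#' Normalize gene symbols
#'
#' Gene symbols in published expression tables mix upper/lower case
#' ("Stub1"/"STUB1"), stray whitespace and Greek letters ("CAMK2α").
#' Normalization strips surrounding whitespace, transliterates Greek letters
#' by a fixed table (α -> A, β -> B, γ -> G), upper-cases the
#' result and finally applies an optional user-supplied alias map
#' (old symbol -> canonical symbol, matched after case folding). The
#' operation is idempotent and case-insensitive; aliasing is never guessed.
#'
#' @param raw character vector of raw symbols.
#' @param aliases optional named character vector mapping upper-cased old
#'   symbols to their canonical replacement (e.g. \code{c(GANP = "MCM3AP")}).
#' @return character vector of normalized symbols.
#' @examples
#' normalizeSymbol(c("Dusp12", " stub1 ", "CAMK2α"))
#' @export
normalizeSymbol <- function(raw, aliases = NULL) {
  if (length(raw) == 0) return(character())
  if (!is.character(raw)) raw <- as.character(raw)
  x <- trimws(raw)
  if (any(is.na(x)) || any(!nzchar(x)))
    stop("invalid symbol: empty or whitespace-only input")
  x <- chartr("αβγΑΒΓ", "ABGABG", x)
  x <- toupper(x)
  if (!is.null(aliases)) {
    if (is.null(names(aliases)) || any(!nzchar(names(aliases))))
      stop("aliases must be a named character vector (old -> canonical)")
    key <- toupper(names(aliases))
    hit <- match(x, key)
    x[!is.na(hit)] <- toupper(trimws(aliases[hit[!is.na(hit)]]))
  }
  x
}
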