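#' Normalize a metadata term for comparison
#'
#' All term comparison in the package happens in a normalized space: terms are
#' lower-cased, trimmed, internal whitespace runs are collapsed to a single
#' space, and the punctuation characters `_ . , ; : / ( ) -` are replaced by a
#' space before re-collapsing. Canonical terms keep their original casing for
#' display; only lookups and collision checks use the normalized form.
#'
#' The function is pure and idempotent: `normalize_term(normalize_term(x))`
#' equals `normalize_term(x)` for any input.
#'
#' @param raw Character vector of raw terms (may be empty strings).
#' @return Character vector of normalized terms, same length as `raw`.
#' @examples
#' normalize_term("  Race ")            # "race"
#' normalize_term("African-American")   # "african american"
#' @export
normalize_term <- function(raw) {
  if (length(raw) == 0L) return(character(0))
  x <- tolower(as.character(raw))
  x[is.na(x)] <- ""
  x <- gsub("[_.,;:/()-]", " ", x)
  x <- gsub("[[:space:]]+", " ", x)
  trimws(x)
}

# Default tokens treated as missing values in cells, compared after
# normalization of both sides.
missing_tokens_default <- function() c("", "NA", "N/A", "na", "null", "-")

#' Test whether cell values count as missing
#'
#' Missing-value semantics drive duplicate-column coalescing and the
#' per-unique-value harmonization stage. A cell is missing when its normalized
#' form equals the normalized form of one of the configured missing tokens
#' (defaults: `""`, `"NA"`, `"N/A"`, `"na"`, `"null"`, `"-"`) or is `NA`.
#'
#' @param x Character vector of cell values.
#' @param missing_tokens Character vector of tokens to treat as missing.
#' @return Logical vector.
#' @export
is_missing_cell <- function(x, missing_tokens = missing_tokens_default()) {
  is.na(x) | normalize_term(x) %in% unique(normalize_term(missing_tokens))
}
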