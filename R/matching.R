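#' Token-set similarity between normalized terms
#'
#' Similarity used for fuzzy candidate ranking: both terms are normalized,
#' their whitespace tokens are deduplicated and sorted, rejoined with single
#' spaces, and scored as `1 - d / max(nchar)` where `d` is the Levenshtein
#' distance between the rejoined strings. Two empty strings score 1; an empty
#' string against a non-empty one scores 0. Token-set treatment makes word
#' order and repeated words irrelevant ("american african" matches
#' "african american" exactly).
#'
#' @param a Single query term (raw text; normalized internally).
#' @param b Character vector of candidate terms.
#' @return Numeric vector of similarities in `[0, 1]`.
#' @export
term_similarity <- function(a, b) {
  if (length(b) == 0L) return(numeric(0))
  canon <- function(x) {
    vapply(normalize_term(x), function(s) {
      toks <- strsplit(s, " ", fixed = TRUE)[[1]]
      paste(sort(unique(toks[nzchar(toks)])), collapse = " ")
    }, character(1), USE.NAMES = FALSE)
  }
  a2 <- canon(a)
  b2 <- canon(b)
  d <- as.integer(utils::adist(a2, b2))
  mx <- pmax(nchar(a2), nchar(b2))
  out <- ifelse(mx == 0L, 1, 1 - d / mx)
  pmin(pmax(out, 0), 1)
}

# Construct a match result. `candidates` is a tibble(canonical_key, score),
# ranked best-first.
new_match_result <- function(query, canonical_key = NA_character_,
                             match_kind = c("none", "exact", "normalized", "fuzzy"),
                             score = 0, ambiguous = FALSE,
                             candidates = NULL) {
  match_kind <- match.arg(match_kind)
  if (is.null(candidates)) {
    candidates <- tibble::tibble(canonical_key = character(0), score = numeric(0))
  }
  structure(
    list(query = query, canonical_key = canonical_key, match_kind = match_kind,
         score = score, ambiguous = ambiguous, candidates = candidates),
    class = "tgx_match"
  )
}

#' @export
print.tgx_match <- function(x, ...) {
  hit <- if (is.na(x$canonical_key)) "<no match>" else x$canonical_key
  cat(sprintf("<tgx_match> '%s' -> %s [%s, score %.3f%s]\n",
              x$query, hit, x$match_kind, x$score,
              if (x$ambiguous) ", ambiguous" else ""))
  invisible(x)
}

# Shared resolution engine over a term index.
#
# `index` is a data frame with columns `term` (raw synonym or canonical text)
# and `canonical` (the canonical key it resolves to). Resolution order:
#  1. exact:      query identical to an indexed term;
#  2. normalized: normalize_term(query) equals a normalized indexed term;
#  3. fuzzy:      best term_similarity >= fuzzy_threshold (NEVER auto-applied
#                 by callers; fuzzy hits only ever become proposals).
# Ties at the top fuzzy score across distinct canonical keys set
# `ambiguous = TRUE` and leave `canonical_key` absent: the tool never guesses
# for the user.
resolve_term <- function(index, term, fuzzy_threshold = 0.85) {
  stopifnot(length(term) == 1L)
  if (nrow(index) == 0L) return(new_match_result(term))

  hit <- index$canonical[index$term == term]
  if (length(hit) > 0L) {
    return(new_match_result(
      term, canonical_key = hit[[1]], match_kind = "exact", score = 1,
      candidates = tibble::tibble(canonical_key = hit[[1]], score = 1)))
  }

  nterm <- normalize_term(term)
  nindex <- normalize_term(index$term)
  hit <- unique(index$canonical[nindex == nterm])
  if (length(hit) > 0L) {
    # a valid vocabulary has no normalized collisions, so hit is length 1
    return(new_match_result(
      term, canonical_key = hit[[1]], match_kind = "normalized", score = 1,
      candidates = tibble::tibble(canonical_key = hit[[1]], score = 1)))
  }

  if (fuzzy_threshold > 1) return(new_match_result(term))
  sims <- term_similarity(term, index$term)
  per_key <- tibble::tibble(canonical_key = index$canonical, score = sims) |>
    dplyr::group_by(.data$canonical_key) |>
    dplyr::summarise(score = max(.data$score), .groups = "drop") |>
    dplyr::filter(.data$score >= fuzzy_threshold) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$canonical_key)
  if (nrow(per_key) == 0L) return(new_match_result(term))

  top <- per_key$score[[1]]
  tied <- sum(per_key$score == top)
  if (tied > 1L) {
    new_match_result(term, match_kind = "fuzzy", score = top,
                     ambiguous = TRUE, candidates = per_key)
  } else {
    new_match_result(term, canonical_key = per_key$canonical_key[[1]],
                     match_kind = "fuzzy", score = top, candidates = per_key)
  }
}
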