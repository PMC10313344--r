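#' Controlled vocabularies
#'
#' A vocabulary is two linked layers of canonical-term-to-synonym maps: a map
#' from canonical metadata *features* (column concepts such as `ethnicity`) to
#' their synonyms, where each feature is in turn linked to a map from its
#' canonical *instances* (the values that feature may take, such as `Black`)
#' to instance synonyms. A canonical term is implicitly a synonym of itself.
#' All uniqueness constraints are enforced in normalized space
#' ([normalize_term()]) while canonical terms keep their display casing.
#'
#' @param name Display name of the vocabulary.
#' @param version Free-text version tag.
#' @param features Named list; each element a feature entry created with
#'   [feature_entry()]. Names must equal the entries' canonical names.
#' @param provenance_note Free-text note on where the vocabulary comes from.
#' @return A `tgx_vocabulary` object.
#' @seealso [load_vocabulary()], [validate_vocabulary()], [lookup_feature()]
#' @examples
#' v <- vocabulary(
#'   name = "demo", version = "1",
#'   features = list(ethnicity = feature_entry(
#'     "ethnicity", synonyms = "race",
#'     instances = list(Black = c("B", "African-American"),
#'                      White = c("Caucasian", "C"),
#'                      Inuit = character(0)))))
#' lookup_feature(v, "race")$canonical_key
#' @export
vocabulary <- function(name = "vocabulary", version = "1",
                       features = list(), provenance_note = "") {
  v <- structure(
    list(name = name, version = version, provenance_note = provenance_note,
         features = features),
    class = "tgx_vocabulary")
  viol <- validate_vocabulary(v)
  if (length(viol) > 0L) {
    stop(errorCondition(
      paste0("invalid vocabulary:\n", paste("-", viol, collapse = "\n")),
      class = c("tgx_vocab_error", "error", "condition")))
  }
  v
}

#' @rdname vocabulary
#' @param canonical_name Canonical display text of the feature.
#' @param synonyms Character vector of feature synonyms (may be empty).
#' @param instances Named list mapping canonical instance text to a character
#'   vector of instance synonyms (possibly empty, as for an instance with no
#'   alternative spellings).
#' @export
feature_entry <- function(canonical_name, synonyms = character(0),
                          instances = list()) {
  stopifnot(is.character(canonical_name), length(canonical_name) == 1L)
  instances <- lapply(instances, as.character)
  structure(
    list(canonical_name = canonical_name,
         synonyms = as.character(synonyms),
         instances = instances),
    class = "tgx_feature_entry")
}

#' @export
print.tgx_vocabulary <- function(x, ...) {
  cat(sprintf("<tgx_vocabulary> '%s' v%s: %d feature(s)\n",
              x$name, x$version, length(x$features)))
  for (f in x$features) {
    cat(sprintf("  %s (%d synonym(s), %d instance(s))\n",
                f$canonical_name, length(f$synonyms), length(f$instances)))
  }
  invisible(x)
}

#' Validate a vocabulary's structural invariants
#'
#' Checks every uniqueness constraint the vocabulary must satisfy for term
#' resolution to be a function: canonical feature keys unique after
#' normalization; no normalized feature synonym resolving to more than one
#' canonical feature; within each feature, canonical instances unique after
#' normalization and no normalized instance synonym attached to more than one
#' canonical instance. A canonical term counts as a synonym of itself.
#'
#' @param v A `tgx_vocabulary` (or structurally identical list).
#' @return Character vector of human-readable violations; empty when valid.
#' @export
validate_vocabulary <- function(v) {
  viol <- character(0)
  feats <- v$features
  if (length(feats) == 0L) return(viol)

  keys <- vapply(feats, function(f) f$canonical_name, character(1))
  if (!identical(unname(keys), names(feats)) &&
      !all(names(feats) == unname(keys))) {
    viol <- c(viol, sprintf(
      "feature list names do not match canonical names: %s",
      paste(names(feats)[names(feats) != unname(keys)], collapse = ", ")))
  }

  nkeys <- normalize_term(keys)
  dup <- unique(nkeys[duplicated(nkeys)])
  for (d in dup) {
    viol <- c(viol, sprintf(
      "canonical feature keys collide after normalization ('%s'): %s",
      d, paste(keys[nkeys == d], collapse = ", ")))
  }

  # feature-level synonym collisions (canonical keys are self-synonyms)
  syn <- feature_index(v)
  nsyn <- normalize_term(syn$term)
  for (d in unique(nsyn[duplicated(nsyn)])) {
    owners <- unique(syn$canonical[nsyn == d])
    if (length(owners) > 1L) {
      viol <- c(viol, sprintf(
        "feature synonym '%s' maps to multiple canonical features: %s",
        d, paste(sort(owners), collapse = ", ")))
    }
  }

  for (f in feats) {
    inst <- names(f$instances)
    ninst <- normalize_term(inst)
    for (d in unique(ninst[duplicated(ninst)])) {
      viol <- c(viol, sprintf(
        "feature '%s': canonical instances collide after normalization ('%s'): %s",
        f$canonical_name, d, paste(inst[ninst == d], collapse = ", ")))
    }
    idx <- instance_index_entry(f)
    nidx <- normalize_term(idx$term)
    for (d in unique(nidx[duplicated(nidx)])) {
      owners <- unique(idx$canonical[nidx == d])
      if (length(owners) > 1L) {
        viol <- c(viol, sprintf(
          "feature '%s': instance synonym '%s' maps to multiple canonical instances: %s",
          f$canonical_name, d, paste(sort(owners), collapse = ", ")))
      }
    }
  }
  viol
}

# term/canonical index over features: canonical keys + their synonyms
feature_index <- function(v) {
  if (length(v$features) == 0L) {
    return(tibble::tibble(term = character(0), canonical = character(0)))
  }
  rows <- lapply(v$features, function(f) {
    tibble::tibble(term = c(f$canonical_name, f$synonyms),
                   canonical = f$canonical_name)
  })
  dplyr::bind_rows(rows)
}

instance_index_entry <- function(f) {
  if (length(f$instances) == 0L) {
    return(tibble::tibble(term = character(0), canonical = character(0)))
  }
  rows <- lapply(names(f$instances), function(ci) {
    tibble::tibble(term = c(ci, f$instances[[ci]]), canonical = ci)
  })
  dplyr::bind_rows(rows)
}

#' Resolve a term against the vocabulary's features or instances
#'
#' Resolution proceeds in three gated steps: exact text match, match after
#' [normalize_term()] normalization (both score 1.0), then — only below the
#' identity threshold — fuzzy candidate ranking by [term_similarity()], kept
#' when the best score reaches `fuzzy_threshold`. Fuzzy hits are reported for
#' human validation, never auto-applied by any pipeline in this package. Ties
#' at the top fuzzy score are flagged `ambiguous` with no winning key.
#'
#' @param v A valid `tgx_vocabulary`.
#' @param term Single query term.
#' @param fuzzy_threshold Minimum similarity for fuzzy candidates, in
#'   `[0, 1]`; a value above 1 disables fuzzy matching. Default 0.85.
#' @return A `tgx_match` object: fields `query`, `canonical_key` (NA when
#'   unmatched or ambiguous), `match_kind` (`exact`/`normalized`/`fuzzy`/
#'   `none`), `score`, `ambiguous`, and a ranked `candidates` tibble.
#' @export
lookup_feature <- function(v, term, fuzzy_threshold = 0.85) {
  resolve_term(feature_index(v), term, fuzzy_threshold)
}

#' @rdname lookup_feature
#' @param feature_key Canonical feature whose instance map is searched;
#'   unknown keys are an error.
#' @export
lookup_instance <- function(v, feature_key, term, fuzzy_threshold = 0.85) {
  f <- v$features[[feature_key]]
  if (is.null(f)) {
    stop(sprintf("unknown canonical feature '%s'", feature_key), call. = FALSE)
  }
  resolve_term(instance_index_entry(f), term, fuzzy_threshold)
}

#' Read and write vocabulary files
#'
#' The on-disk format is a single UTF-8 JSON document:
#' `{"name": ..., "version": ..., "features": {<canonical>: {"synonyms":
#' [...], "instances": {<canonical>: [synonyms...]}}}}`. An empty vocabulary
#' has `"features": {}`. Any pre-existing ontology restructured to this shape
#' can be used as the reference vocabulary. Loading validates all invariants
#' and fails with the complete list of violations.
#'
#' @param path File path.
#' @return `load_vocabulary()` returns a validated `tgx_vocabulary`;
#'   `save_vocabulary()` returns `path` invisibly and round-trips: loading a
#'   saved vocabulary reproduces the identical structure.
#' @export
load_vocabulary <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  doc <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop(sprintf("malformed vocabulary file '%s': %s",
                                     path, conditionMessage(e)), call. = FALSE))
  vocabulary_from_list(doc, context = path)
}

vocabulary_from_list <- function(doc, context = "vocabulary") {
  if (!is.list(doc)) {
    stop(sprintf("malformed vocabulary '%s': top level must be an object",
                 context), call. = FALSE)
  }
  feats <- doc$features
  if (is.null(feats)) feats <- list()
  entries <- lapply(names(feats), function(key) {
    fe <- feats[[key]]
    syn <- as.character(unlist(fe$synonyms))
    inst_raw <- fe$instances
    if (is.null(inst_raw)) inst_raw <- list()
    inst <- lapply(inst_raw, function(s) as.character(unlist(s)))
    names(inst) <- names(inst_raw)
    feature_entry(key, synonyms = syn, instances = inst)
  })
  names(entries) <- names(feats)
  v <- structure(
    list(name = doc$name %||% "vocabulary",
         version = as.character(doc$version %||% "1"),
         provenance_note = doc$provenance_note %||% "",
         features = entries),
    class = "tgx_vocabulary")
  viol <- validate_vocabulary(v)
  if (length(viol) > 0L) {
    stop(errorCondition(
      sprintf("invalid vocabulary '%s':\n%s", context,
              paste("-", viol, collapse = "\n")),
      class = c("tgx_vocab_error", "error", "condition")))
  }
  v
}

vocabulary_to_list <- function(v) {
  feats <- lapply(v$features, function(f) {
    list(synonyms = as.list(f$synonyms),
         instances = lapply(f$instances, as.list))
  })
  names(feats) <- names(v$features)
  list(name = v$name, version = v$version,
       provenance_note = v$provenance_note, features = feats)
}

#' @rdname load_vocabulary
#' @param v A valid `tgx_vocabulary`.
#' @export
save_vocabulary <- function(v, path) {
  viol <- validate_vocabulary(v)
  if (length(viol) > 0L) {
    stop(errorCondition(
      paste0("refusing to save invalid vocabulary:\n",
             paste("-", viol, collapse = "\n")),
      class = c("tgx_vocab_error", "error", "condition")))
  }
  write_json_atomic(vocabulary_to_list(v), path)
  invisible(path)
}

# structural equality ignoring environment/attribute noise
vocab_identical <- function(a, b) {
  identical(vocabulary_to_list(a), vocabulary_to_list(b))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Atomic JSON writer: no artifact is ever partially written.
write_json_atomic <- function(x, path, ...) {
  tmp <- paste0(path, ".tmp", Sys.getpid())
  jsonlite::write_json(x, tmp, auto_unbox = TRUE, null = "null", na = "null",
                       pretty = TRUE, digits = NA, ...)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}
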