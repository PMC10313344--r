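#' Temporary (staging) vocabularies
#'
#' Terms met during curation that do not resolve in the reference vocabulary
#' are staged here, pending a human decision. Each staged entry records what
#' kind of term it is (a new feature or a new instance of an existing
#' feature), the dataset it came from, a creation timestamp, and a status in
#' `{pending, approved, rejected}` — the same amber/green/red colour coding
#' used for dataset integration. Only approved entries can be promoted into
#' the reference vocabulary; a term already resolvable in the reference
#' vocabulary can never be staged.
#'
#' @param name Display name.
#' @param version Version tag.
#' @return An empty `tgx_temp_vocabulary`.
#' @seealso [stage_term()], [merge_temp()]
#' @export
temp_vocabulary <- function(name = "temporary vocabulary", version = "1") {
  structure(
    list(name = name, version = version,
         entries = tibble::tibble(
           entry_id = character(0), feature_key = character(0),
           term = character(0), as_kind = character(0),
           status = character(0), origin_dataset = character(0),
           created_at = character(0))),
    class = "tgx_temp_vocabulary")
}

#' @export
print.tgx_temp_vocabulary <- function(x, ...) {
  n <- table(factor(x$entries$status,
                    levels = c("pending", "approved", "rejected")))
  cat(sprintf("<tgx_temp_vocabulary> %d entr%s (%d pending, %d approved, %d rejected)\n",
              nrow(x$entries), if (nrow(x$entries) == 1) "y" else "ies",
              n[["pending"]], n[["approved"]], n[["rejected"]]))
  invisible(x)
}

temp_entry_id <- function(feature_key, term, as_kind) {
  if (as_kind == "feature") {
    paste0("feature:", normalize_term(term))
  } else {
    paste0("instance:", normalize_term(feature_key), ":", normalize_term(term))
  }
}

#' Stage an unmatched term in the temporary vocabulary
#'
#' Adds a pending entry for a term that the reference vocabulary cannot
#' resolve (exactly or after normalization). Staging a resolvable term is an
#' error — the temporary vocabulary never shadows the reference — as is
#' staging the same term twice. Vocabulary values are immutable: the input is
#' returned unchanged and a new object carries the entry.
#'
#' @param t A `tgx_temp_vocabulary`.
#' @param v The reference `tgx_vocabulary` the term failed to resolve in.
#' @param feature_key For `as_kind = "instance"`, the canonical feature the
#'   new instance belongs to; ignored for new features.
#' @param term The unmatched raw term.
#' @param as_kind `"feature"` or `"instance"`.
#' @param origin_dataset Dataset identifier the term was observed in.
#' @return A new `tgx_temp_vocabulary` with the pending entry appended.
#' @export
stage_term <- function(t, v, feature_key = NA_character_, term,
                       as_kind = c("instance", "feature"),
                       origin_dataset = "") {
  as_kind <- match.arg(as_kind)
  if (as_kind == "feature") {
    m <- lookup_feature(v, term, fuzzy_threshold = 2)
    if (m$match_kind != "none") {
      stop(sprintf("'%s' is already in the reference vocabulary (resolves to feature '%s')",
                   term, m$canonical_key), call. = FALSE)
    }
  } else {
    if (is.na(feature_key) || is.null(v$features[[feature_key]])) {
      stop(sprintf("unknown canonical feature '%s'", feature_key), call. = FALSE)
    }
    m <- lookup_instance(v, feature_key, term, fuzzy_threshold = 2)
    if (m$match_kind != "none") {
      stop(sprintf("'%s' is already in the reference vocabulary (resolves to instance '%s' of '%s')",
                   term, m$canonical_key, feature_key), call. = FALSE)
    }
  }
  id <- temp_entry_id(feature_key, term, as_kind)
  if (id %in% t$entries$entry_id) {
    stop(sprintf("term '%s' is already staged (entry '%s')", term, id),
         call. = FALSE)
  }
  t$entries <- dplyr::bind_rows(t$entries, tibble::tibble(
    entry_id = id,
    feature_key = if (as_kind == "instance") feature_key else NA_character_,
    term = term, as_kind = as_kind, status = "pending",
    origin_dataset = origin_dataset, created_at = utc_now()))
  t
}

#' Merge approved temporary-vocabulary entries into the reference vocabulary
#'
#' Every pending entry must carry a decision. Approved entries are inserted
#' into a copy of the reference vocabulary — new features with empty synonym
#' sets, new instances under their feature — which must re-validate cleanly;
#' any collision aborts the whole merge with no partial change. Rejected
#' entries stay in the temporary vocabulary with status `rejected`; approved
#' entries leave it (they now live in the reference vocabulary). Given the
#' same decisions the merge is deterministic.
#'
#' @param v Reference `tgx_vocabulary`.
#' @param t `tgx_temp_vocabulary` with pending entries.
#' @param decisions Named character vector `entry_id -> "approve"|"reject"`.
#' @return List with elements `vocabulary` (new reference) and `temp`
#'   (updated temporary vocabulary).
#' @export
merge_temp <- function(v, t, decisions) {
  pend <- t$entries[t$entries$status == "pending", , drop = FALSE]
  missing <- setdiff(pend$entry_id, names(decisions))
  if (length(missing) > 0L) {
    stop("missing decision for pending entr(ies): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(unname(decisions)), c("approve", "reject"))
  if (length(bad) > 0L) {
    stop("decisions must be 'approve' or 'reject', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }

  v2 <- v
  for (i in seq_len(nrow(pend))) {
    e <- pend[i, ]
    if (decisions[[e$entry_id]] != "approve") next
    if (e$as_kind == "feature") {
      v2$features[[e$term]] <- feature_entry(e$term)
    } else {
      f <- v2$features[[e$feature_key]]
      if (is.null(f)) {
        stop(sprintf("entry '%s': feature '%s' not present in vocabulary",
                     e$entry_id, e$feature_key), call. = FALSE)
      }
      f$instances[[e$term]] <- character(0)
      v2$features[[e$feature_key]] <- f
    }
  }
  viol <- validate_vocabulary(v2)
  if (length(viol) > 0L) {
    stop("merge would create an invalid vocabulary (no entries merged):\n",
         paste("-", viol, collapse = "\n"), call. = FALSE)
  }

  ent <- t$entries
  decided <- ent$entry_id %in% pend$entry_id
  verdict <- ifelse(decided, unname(decisions[ent$entry_id]), NA_character_)
  keep <- !(decided & verdict == "approve")
  ent$status[decided & verdict == "reject"] <- "rejected"
  t$entries <- ent[keep, , drop = FALSE]
  list(vocabulary = v2, temp = t)
}

# exact/normalized resolution against the temp vocabulary (no fuzzy):
# is this term staged (pending or approved) as a feature / as an instance of
# feature_key?
temp_resolves <- function(t, term, as_kind, feature_key = NA_character_) {
  ent <- t$entries[t$entries$status %in% c("pending", "approved") &
                     t$entries$as_kind == as_kind, , drop = FALSE]
  if (as_kind == "instance") {
    ent <- ent[!is.na(ent$feature_key) &
                 normalize_term(ent$feature_key) == normalize_term(feature_key), ,
               drop = FALSE]
  }
  any(normalize_term(ent$term) == normalize_term(term))
}

utc_now <- function() {
  format(Sys.time(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
}
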