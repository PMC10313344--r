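#' Single-dataset curation
#'
#' Curation of one metadata table runs in three monotone stages:
#' \describe{
#'   \item{rename}{consistent renaming of table columns against the
#'     vocabulary's canonical features;}
#'   \item{dedup}{resolution of duplicate columns (same canonicalized
#'     header);}
#'   \item{values}{harmonization of the unique values of each canonical
#'     column against that feature's instances.}
#' }
#' Nothing is ever changed silently: every stage generates *proposals*, each
#' of which a human (or a scripted decision file) accepts, rejects or edits;
#' only accepted/edited proposals touch the working table and each applied
#' change is audited first. The original table is never modified. Terms the
#' vocabulary cannot resolve are collected via [unmatched_terms()] and staged
#' in the temporary vocabulary.
#'
#' @param table A `tgx_table` to curate.
#' @param glp_mode Run under GLP rules: every decision requires a non-blank
#'   justification, enforced before any state changes.
#' @param actor Curator name for the audit trail.
#' @param temp_vocab Optional existing `tgx_temp_vocabulary` to continue
#'   filling.
#' @param audit Optional existing `tgx_audit_log` to append to.
#' @param missing_tokens Cell texts treated as missing (see
#'   [is_missing_cell()]).
#' @return A `tgx_curation` state object.
#' @seealso [propose_column_renames()], [detect_duplicate_columns()],
#'   [propose_value_harmonization()], [apply_decision()], [curated_table()]
#' @export
new_curation <- function(table, glp_mode = FALSE, actor = default_actor(),
                         temp_vocab = NULL, audit = NULL,
                         missing_tokens = missing_tokens_default()) {
  stopifnot(inherits(table, "tgx_table"))
  structure(
    list(original = table, working = table,
         proposals = empty_proposals(), stage = "rename",
         temp_vocab = temp_vocab %||% temp_vocabulary(),
         audit = audit %||% audit_log(),
         glp_mode = isTRUE(glp_mode), actor = actor,
         missing_tokens = missing_tokens),
    class = "tgx_curation")
}

curation_stages <- function() c("rename", "dedup", "values", "done")

empty_proposals <- function() {
  tibble::tibble(
    proposal_id = character(0), kind = character(0), col_index = integer(0),
    target_column = character(0), current = character(0),
    suggested = character(0), match_kind = character(0), score = numeric(0),
    ambiguous = logical(0), status = character(0), edited_value = character(0))
}

#' @export
print.tgx_curation <- function(x, ...) {
  cat(sprintf("<tgx_curation> dataset '%s', stage '%s'%s\n",
              dataset_id(x$original), x$stage,
              if (x$glp_mode) " [GLP]" else ""))
  if (nrow(x$proposals) > 0L) {
    tab <- table(x$proposals$status)
    cat("  proposals:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  cat(sprintf("  audit records: %d\n", nrow(x$audit$records)))
  invisible(x)
}

require_stage <- function(s, stage) {
  if (!identical(s$stage, stage)) {
    stop(sprintf("operation belongs to stage '%s' but the session is in stage '%s' (stages are monotone: %s)",
                 stage, s$stage, paste(curation_stages(), collapse = " -> ")),
         call. = FALSE)
  }
}

#' Advance the curation state to its next stage
#'
#' Stages move only forward (`rename -> dedup -> values -> done`) and only
#' when no proposal of the current stage is still pending.
#'
#' @param s A `tgx_curation`.
#' @return The state with `stage` advanced by one.
#' @export
advance_stage <- function(s) {
  stages <- curation_stages()
  i <- match(s$stage, stages)
  if (i == length(stages)) stop("curation is already done", call. = FALSE)
  pending <- s$proposals$status == "pending"
  if (any(pending)) {
    stop("cannot advance stage with pending proposals: ",
         paste(s$proposals$proposal_id[pending], collapse = ", "),
         call. = FALSE)
  }
  s$stage <- stages[[i + 1L]]
  s
}

#' Propose canonical renames for every column header
#'
#' Stage (i) of curation. Generates one proposal per column, in column order,
#' by resolving each header with [lookup_feature()]: exact/normalized hits
#' suggest the canonical feature (an already-canonical header yields an
#' auto-acceptable no-op), fuzzy hits suggest the top candidate for human
#' confirmation, and unresolvable headers get no suggestion — they are
#' candidates for [stage_term()]. Proposal identifiers are deterministic in
#' (stage, column position, normalized header) so decision files are stable
#' across runs.
#'
#' @param s A `tgx_curation` in stage `rename`.
#' @param v The reference vocabulary.
#' @param fuzzy_threshold Passed to [lookup_feature()].
#' @return The state with rename proposals added (existing decisions on
#'   identical proposals are preserved if called twice).
#' @export
propose_column_renames <- function(s, v, fuzzy_threshold = 0.85) {
  require_stage(s, "rename")
  hdr <- names(s$working)
  rows <- lapply(seq_along(hdr), function(i) {
    m <- lookup_feature(v, hdr[[i]], fuzzy_threshold)
    tibble::tibble(
      proposal_id = sprintf("rename:%03d:%s", i, normalize_term(hdr[[i]])),
      kind = "rename_column", col_index = i, target_column = hdr[[i]],
      current = hdr[[i]],
      suggested = if (m$ambiguous) NA_character_ else m$canonical_key,
      match_kind = m$match_kind, score = m$score, ambiguous = m$ambiguous,
      status = "pending", edited_value = NA_character_)
  })
  add_proposals(s, dplyr::bind_rows(rows))
}

add_proposals <- function(s, new) {
  keep <- !(new$proposal_id %in% s$proposals$proposal_id)
  s$proposals <- dplyr::bind_rows(s$proposals, new[keep, , drop = FALSE])
  s
}

#' Detect duplicate columns
#'
#' Stage (ii). Columns are duplicates when their canonicalized (normalized)
#' headers are equal — content only decides whether a merge is safe. For each
#' group the per-row agreement summary states whether all non-missing cells
#' of that row agree.
#'
#' @param s A `tgx_curation` in stage `dedup` (headers already renamed).
#' @return List of duplicate groups; each a list with `header` (normalized),
#'   `headers` (display texts), `positions` (column indices) and `agreement`
#'   (logical per row; `TRUE` when the row's non-missing cells agree,
#'   vacuously `TRUE` with fewer than two non-missing cells).
#' @export
detect_duplicate_columns <- function(s) {
  require_stage(s, "dedup")
  t <- s$working
  nh <- normalize_term(names(t))
  groups <- split(seq_along(nh), nh)
  groups <- groups[vapply(groups, length, integer(1)) >= 2L]
  unname(lapply(names(groups), function(h) {
    pos <- groups[[h]]
    agreement <- vapply(seq_len(nrow(t)), function(r) {
      cells <- vapply(pos, function(p) t[[p]][[r]], character(1))
      cells <- cells[!is_missing_cell(cells, s$missing_tokens)]
      length(unique(cells)) <= 1L
    }, logical(1))
    list(header = h, headers = names(t)[pos], positions = pos,
         agreement = agreement)
  }))
}

#' Resolve a duplicate-column group
#'
#' Stage (ii). Decisions: `keep_first_fill_missing` coalesces the group into
#' its first column cell-wise (first non-missing value wins; any row with two
#' disagreeing non-missing values blocks the merge and must be edited first);
#' `keep_named_column` keeps one column (by position within the group) and
#' drops the rest; `keep_all` leaves the table unchanged. All three outcomes
#' are audited before the table changes.
#'
#' @param s A `tgx_curation` in stage `dedup`.
#' @param group A group from [detect_duplicate_columns()] on this state.
#' @param decision One of `keep_first_fill_missing`, `keep_named_column`,
#'   `keep_all`.
#' @param keep For `keep_named_column`: the column position (in the full
#'   table) to keep.
#' @param justification Audit justification (mandatory in GLP mode).
#' @return The updated state.
#' @export
resolve_duplicates <- function(s, group,
                               decision = c("keep_first_fill_missing",
                                            "keep_named_column", "keep_all"),
                               keep = NULL, justification = NA_character_) {
  require_stage(s, "dedup")
  decision <- match.arg(decision)
  t <- s$working
  pos <- group$positions
  if (max(pos) > ncol(t) ||
      !identical(normalize_term(names(t)[pos]),
                 rep(group$header, length(pos)))) {
    stop("duplicate group does not match the current working table; re-run detect_duplicate_columns()",
         call. = FALSE)
  }

  if (decision == "keep_all") {
    s$audit <- record(s$audit, "reject", actor = s$actor,
                      dataset_id = dataset_id(s$original),
                      target = paste0("duplicate-group:", group$header),
                      before = json_payload(pos),
                      justification = justification, glp_mode = s$glp_mode)
    return(s)
  }

  if (decision == "keep_first_fill_missing") {
    conflict <- which(vapply(seq_len(nrow(t)), function(r) {
      cells <- vapply(pos, function(p) t[[p]][[r]], character(1))
      cells <- cells[!is_missing_cell(cells, s$missing_tokens)]
      length(unique(cells)) > 1L
    }, logical(1)))
    if (length(conflict) > 0L) {
      stop(sprintf("cannot merge duplicate columns '%s': conflicting non-missing values in row(s) %s; edit them first",
                   group$header, paste(conflict, collapse = ", ")),
           call. = FALSE)
    }
    s$audit <- record(s$audit, "merge", actor = s$actor,
                      dataset_id = dataset_id(s$original),
                      target = paste0("duplicate-group:", group$header),
                      before = json_payload(pos),
                      after = json_payload(pos[[1]]),
                      justification = justification, glp_mode = s$glp_mode)
    s$working <- coalesce_columns(t, pos, s$missing_tokens)
    return(s)
  }

  # keep_named_column
  if (is.null(keep) || !keep %in% pos) {
    stop("keep_named_column requires `keep`, a column position inside the group",
         call. = FALSE)
  }
  drop <- setdiff(pos, keep)
  s$audit <- record(s$audit, "delete", actor = s$actor,
                    dataset_id = dataset_id(s$original),
                    target = paste0("duplicate-group:", group$header),
                    before = json_payload(drop),
                    after = json_payload(keep),
                    justification = justification, glp_mode = s$glp_mode)
  s$working <- drop_columns(t, drop)
  s
}

# first non-missing value wins, group collapses onto its first position
coalesce_columns <- function(t, pos, missing_tokens) {
  merged <- vapply(seq_len(nrow(t)), function(r) {
    cells <- vapply(pos, function(p) t[[p]][[r]], character(1))
    nm <- cells[!is_missing_cell(cells, missing_tokens)]
    if (length(nm) == 0L) cells[[1]] else nm[[1]]
  }, character(1))
  t[[pos[[1]]]] <- merged
  drop_columns(t, pos[-1])
}

drop_columns <- function(t, drop) {
  keep <- setdiff(seq_along(names(t)), drop)
  out <- t[, keep, drop = FALSE]
  # subsetting can repair duplicate names; restore them
  names(out) <- names(t)[keep]
  attr(out, "dataset_id") <- dataset_id(t)
  attr(out, "source_path") <- attr(t, "source_path", exact = TRUE)
  if (!inherits(out, "tgx_table")) class(out) <- c("tgx_table", class(out))
  out
}

#' Propose harmonized replacements for a column's unique values
#'
#' Stage (iii). For one canonical column, generates exactly one proposal per
#' *unique* non-missing cell value (never per cell) by resolving the value
#' with [lookup_instance()] against that feature's instance map. Accepting a
#' proposal later rewrites every cell equal to that value. Columns whose
#' header is not a canonical feature of the vocabulary cannot be harmonized
#' here — rename them in stage (i) or leave them untouched.
#'
#' @param s A `tgx_curation` in stage `values`.
#' @param column Column position, or header text of a unique column.
#' @param v Reference vocabulary.
#' @param fuzzy_threshold Passed to [lookup_instance()].
#' @return The state with value proposals added.
#' @export
propose_value_harmonization <- function(s, column, v, fuzzy_threshold = 0.85) {
  require_stage(s, "values")
  t <- s$working
  i <- resolve_column(t, column)
  hdr <- names(t)[[i]]
  key <- canonical_feature_of(v, hdr)
  if (is.na(key)) {
    stop(sprintf("column '%s' is not a canonical feature of the vocabulary; rename it in stage (i) first",
                 hdr), call. = FALSE)
  }
  vals <- t[[i]]
  uniq <- unique(vals[!is_missing_cell(vals, s$missing_tokens)])
  # raw-distinct values may share a normalized form; ids disambiguate by
  # order of first appearance so they stay stable across runs
  ids <- sprintf("value:%03d:%s", i, normalize_term(uniq))
  dup_ord <- stats::ave(seq_along(ids), ids, FUN = seq_along)
  ids <- ifelse(dup_ord > 1L, paste0(ids, ":", dup_ord), ids)
  rows <- lapply(seq_along(uniq), function(k) {
    val <- uniq[[k]]
    m <- lookup_instance(v, key, val, fuzzy_threshold)
    tibble::tibble(
      proposal_id = ids[[k]],
      kind = "replace_value", col_index = i, target_column = hdr,
      current = val,
      suggested = if (m$ambiguous) NA_character_ else m$canonical_key,
      match_kind = m$match_kind, score = m$score, ambiguous = m$ambiguous,
      status = "pending", edited_value = NA_character_)
  })
  add_proposals(s, dplyr::bind_rows(rows))
}

resolve_column <- function(t, column) {
  if (is.numeric(column)) {
    i <- as.integer(column)
    if (i < 1L || i > ncol(t)) stop("column position out of range", call. = FALSE)
    return(i)
  }
  hits <- which(names(t) == column)
  if (length(hits) == 0L) stop(sprintf("no column named '%s'", column), call. = FALSE)
  if (length(hits) > 1L) {
    stop(sprintf("column name '%s' is ambiguous (duplicates unresolved); use a position",
                 column), call. = FALSE)
  }
  hits[[1]]
}

# canonical feature key whose normalized form equals the header's, or NA
canonical_feature_of <- function(v, header) {
  keys <- names(v$features)
  hit <- keys[normalize_term(keys) == normalize_term(header)]
  if (length(hit) == 0L) NA_character_ else hit[[1]]
}

#' Decide on a pending proposal
#'
#' The single gate through which curation changes data. `accept` applies the
#' proposal's suggestion, `edit` applies a user-supplied value, `reject`
#' changes nothing; all three are audited, and the audit append happens
#' *before* any mutation, so a GLP justification failure leaves the state
#' untouched. Accepting a `replace_value` proposal rewrites every cell of the
#' column equal to the proposal's unique value. Accepting a no-op proposal
#' (suggestion identical to the current text) is recorded with identical
#' before/after fields.
#'
#' @param s A `tgx_curation`.
#' @param proposal_id Identifier of a pending proposal.
#' @param decision `"accept"`, `"reject"` or `"edit"`.
#' @param edited_value Replacement text, required for `edit`.
#' @param justification Mandatory non-blank text in GLP mode.
#' @return The updated state.
#' @export
apply_decision <- function(s, proposal_id,
                           decision = c("accept", "reject", "edit"),
                           edited_value = NULL,
                           justification = NA_character_) {
  decision <- match.arg(decision)
  idx <- which(s$proposals$proposal_id == proposal_id)
  if (length(idx) == 0L) {
    stop(sprintf("unknown proposal '%s'", proposal_id), call. = FALSE)
  }
  p <- s$proposals[idx, ]
  if (p$status != "pending") {
    stop(sprintf("proposal '%s' is not pending (status '%s')",
                 proposal_id, p$status), call. = FALSE)
  }
  if (decision == "edit" && (is.null(edited_value) || !nzchar(edited_value))) {
    stop("edit decision requires a non-empty edited_value", call. = FALSE)
  }
  if (decision == "accept" && is.na(p$suggested)) {
    stop(sprintf("proposal '%s' has no suggestion%s; edit or reject it",
                 proposal_id,
                 if (p$ambiguous) " (ambiguous match)" else ""), call. = FALSE)
  }

  ds <- dataset_id(s$original)
  if (decision == "reject") {
    s$audit <- record(s$audit, "reject", actor = s$actor, dataset_id = ds,
                      target = proposal_id, before = p$current,
                      justification = justification, glp_mode = s$glp_mode)
    s$proposals$status[[idx]] <- "rejected"
    return(s)
  }

  new_value <- if (decision == "edit") edited_value else p$suggested
  kind <- if (p$kind == "rename_column") "rename" else "replace"
  s$audit <- record(s$audit, kind, actor = s$actor, dataset_id = ds,
                    target = if (p$kind == "rename_column")
                      sprintf("column:%d", p$col_index)
                    else sprintf("column:%d:value", p$col_index),
                    before = p$current, after = new_value,
                    justification = justification, glp_mode = s$glp_mode)

  if (p$kind == "rename_column") {
    names(s$working)[[p$col_index]] <- new_value
  } else {
    col <- s$working[[p$col_index]]
    col[col == p$current] <- new_value
    s$working[[p$col_index]] <- col
  }
  s$proposals$status[[idx]] <- if (decision == "edit") "edited" else "accepted"
  if (decision == "edit") s$proposals$edited_value[[idx]] <- edited_value
  s
}

#' Terms the vocabulary could not resolve
#'
#' Collects (column, term) pairs from proposals whose lookup found nothing —
#' the candidates for [stage_term()] into the temporary vocabulary.
#'
#' @param s A `tgx_curation`.
#' @return Tibble with columns `column`, `term`, `kind`, `proposal_id`.
#' @export
unmatched_terms <- function(s) {
  p <- s$proposals
  sel <- p$match_kind == "none" & p$status %in% c("pending", "edited", "rejected")
  tibble::tibble(column = p$target_column[sel], term = p$current[sel],
                 kind = p$kind[sel], proposal_id = p$proposal_id[sel])
}

#' Extract the curated table
#'
#' Only available once curation reached stage `done` with every proposal
#' resolved; pending proposals are an error listing their identifiers. Every
#' header of the result is canonical or explicitly user-edited, every cell
#' original, canonical or user-edited — nothing was changed silently.
#'
#' @param s A `tgx_curation`.
#' @return The curated `tgx_table`.
#' @export
curated_table <- function(s) {
  pending <- s$proposals$proposal_id[s$proposals$status == "pending"]
  if (!identical(s$stage, "done") || length(pending) > 0L) {
    stop("curation is not finished",
         if (length(pending) > 0L)
           paste0("; pending proposals: ", paste(pending, collapse = ", "))
         else paste0(" (stage '", s$stage, "')"),
         call. = FALSE)
  }
  s$working
}

# compact JSON payload for audit record before/after fields
json_payload <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = FALSE))
}

json_unpayload <- function(txt) {
  as.integer(jsonlite::fromJSON(txt))
}
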