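#' Replay an audit log against the original inputs
#'
#' Reproducibility check: starting from the untouched original tables and the
#' starting reference vocabulary, re-executes every audited action step by
#' step and returns the reconstructed curated tables and vocabulary state.
#' Replay is a pure function of its inputs — timestamps play no role — so two
#' replays of the same log are identical, and a replay of a faithful log is
#' structurally identical to the live session's outputs. A record that does
#' not apply cleanly (its target is gone or its before-text does not match)
#' raises an error naming the record's sequence number: the log and the
#' inputs do not belong together.
#'
#' @param originals List of original `tgx_table` objects (one per dataset in
#'   the log).
#' @param v The starting reference `tgx_vocabulary`.
#' @param log The `tgx_audit_log` produced by the live session.
#' @param missing_tokens Missing-cell tokens used during the live run.
#' @return List with `tables` (named by dataset id), `vocabulary` and
#'   `temp_vocab` after all actions.
#' @export
replay <- function(originals, v, log,
                   missing_tokens = missing_tokens_default()) {
  tabs <- stats::setNames(originals,
                          vapply(originals, dataset_id, character(1)))
  temp <- temp_vocabulary()

  fail <- function(seq, msg) {
    stop(sprintf("replay failed at record seq %d: %s (log/input mismatch)",
                 seq, msg), call. = FALSE)
  }

  recs <- log$records[order(log$records$seq), , drop = FALSE]
  for (i in seq_len(nrow(recs))) {
    r <- recs[i, ]
    kind <- r$action_kind
    if (kind %in% c("reject", "issue", "issue_resolve", "session")) next

    if (kind == "stage_term") {
      parts <- strsplit(r$target, ":", fixed = TRUE)[[1]]
      as_kind <- parts[[1]]
      temp <- tryCatch(
        stage_term(temp, v,
                   feature_key = if (as_kind == "instance") r$after else NA_character_,
                   term = r$before, as_kind = as_kind,
                   origin_dataset = r$dataset_id),
        error = function(e) fail(r$seq, conditionMessage(e)))
      next
    }
    if (kind == "vocab_merge") {
      decisions <- unlist(jsonlite::fromJSON(r$before, simplifyVector = TRUE))
      out <- tryCatch(merge_temp(v, temp, decisions),
                      error = function(e) fail(r$seq, conditionMessage(e)))
      v <- out$vocabulary
      temp <- out$temp
      next
    }

    ds <- r$dataset_id
    if (is.na(ds) || is.null(tabs[[ds]])) {
      fail(r$seq, sprintf("no original table for dataset '%s'", ds))
    }
    t <- tabs[[ds]]

    if (kind == "rename") {
      ci <- as.integer(sub("^column:", "", r$target))
      if (is.na(ci) || ci > ncol(t)) fail(r$seq, "column position out of range")
      if (!identical(names(t)[[ci]], r$before)) {
        fail(r$seq, sprintf("expected column %d to be named '%s' but found '%s'",
                            ci, r$before, names(t)[[ci]]))
      }
      names(t)[[ci]] <- r$after
    } else if (kind == "replace") {
      ci <- as.integer(sub("^column:(\\d+):value$", "\\1", r$target))
      if (is.na(ci) || ci > ncol(t)) fail(r$seq, "column position out of range")
      col <- t[[ci]]
      if (!r$before %in% col) {
        fail(r$seq, sprintf("value '%s' not present in column %d", r$before, ci))
      }
      col[col == r$before] <- r$after
      t[[ci]] <- col
    } else if (kind == "merge") {
      pos <- json_unpayload(r$before)
      if (max(pos) > ncol(t)) fail(r$seq, "merge positions out of range")
      t <- coalesce_columns(t, pos, missing_tokens)
    } else if (kind == "delete") {
      pos <- json_unpayload(r$before)
      if (max(pos) > ncol(t)) fail(r$seq, "delete positions out of range")
      t <- drop_columns(t, pos)
    } else {
      fail(r$seq, sprintf("unreplayable action kind '%s'", kind))
    }
    tabs[[ds]] <- t
  }

  list(tables = tabs, vocabulary = v, temp_vocab = temp)
}

#' Generate the session report
#'
#' The human format is a Markdown document listing the session header
#' (identifier, vocabulary name and version, dataset ids, GLP mode), one line
#' per audit record (sequence, timestamp, actor, action, before/after,
#' justification) and the integration summary when present — the full track
#' needed to reconstruct the harmonization step by step. The machine format
#' is a JSON-serializable list that round-trips through
#' [jsonlite::write_json()]/[jsonlite::read_json()].
#'
#' @param s A `tgx_session`.
#' @param format `"human"` or `"machine"`.
#' @param path Optional output path; the document is also returned.
#' @return Character vector of Markdown lines (`human`) or a list
#'   (`machine`).
#' @export
generate_report <- function(s, format = c("human", "machine"), path = NULL) {
  format <- match.arg(format)
  if (format == "machine") {
    doc <- list(
      session_id = s$session_id, glp_mode = s$glp_mode, actor = s$actor,
      created_at = s$created_at,
      vocabulary = list(name = s$vocabulary$name,
                        version = s$vocabulary$version),
      datasets = as.list(names(s$curation_states)),
      records = tibble_to_records(s$audit$records),
      integration = if (is.null(s$integration)) NULL
                    else report_to_list(s$integration$report))
    if (!is.null(path)) write_json_atomic(doc, path)
    return(doc)
  }

  lines <- c(
    sprintf("# Curation report — session %s", s$session_id),
    "",
    sprintf("- Vocabulary: %s (version %s)", s$vocabulary$name,
            s$vocabulary$version),
    sprintf("- Datasets: %s",
            if (length(s$curation_states) == 0L) "(none)"
            else paste(names(s$curation_states), collapse = ", ")),
    sprintf("- GLP mode: %s", if (s$glp_mode) "yes" else "no"),
    sprintf("- Actor: %s", s$actor),
    sprintf("- Created: %s", s$created_at),
    "",
    "## Actions", "")
  recs <- s$audit$records
  if (nrow(recs) == 0L) {
    lines <- c(lines, "(no actions recorded)")
  }
  for (i in seq_len(nrow(recs))) {
    r <- recs[i, ]
    chg <- if (!is.na(r$before) || !is.na(r$after)) {
      sprintf(" '%s' -> '%s'",
              if (is.na(r$before)) "" else r$before,
              if (is.na(r$after)) "" else r$after)
    } else ""
    lines <- c(lines, sprintf(
      "%d. [%s] %s by %s%s%s%s",
      r$seq, r$timestamp, r$action_kind, r$actor,
      if (is.na(r$dataset_id)) "" else sprintf(" on %s", r$dataset_id),
      chg,
      if (is.na(r$justification)) ""
      else sprintf(" — justification: %s", r$justification)))
  }
  if (!is.null(s$integration)) {
    lines <- c(lines, "", "## Integration summary", "")
    fr <- s$integration$report$feature_rows
    for (i in seq_len(nrow(fr))) {
      lines <- c(lines, sprintf("- %s: %s", fr$feature[[i]], fr$status[[i]]))
    }
  }
  if (!is.null(path)) {
    tmp <- paste0(path, ".tmp", Sys.getpid())
    writeLines(lines, tmp, useBytes = TRUE)
    if (!file.rename(tmp, path)) { file.copy(tmp, path, overwrite = TRUE); unlink(tmp) }
  }
  lines
}
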