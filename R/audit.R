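#' GLP-style audit logs
#'
#' Every action taken during curation and integration — including rejections —
#' is appended to an audit log before the action mutates any state. Records
#' carry a gapless sequence number, a UTC timestamp, the actor, the action
#' kind, the affected dataset and target, the before/after values, and the
#' justification. In GLP mode a non-blank justification is mandatory: the
#' append fails and, because callers record before mutating, the action
#' itself does not proceed. Timestamps are recorded for the report but are
#' excluded from replay semantics and structural comparison, so
#' reproducibility never depends on wall-clock.
#'
#' @param session_id Identifier of the owning session.
#' @return `audit_log()` returns an empty `tgx_audit_log`.
#' @seealso [record()], [replay()]
#' @export
audit_log <- function(session_id = "session") {
  structure(
    list(session_id = session_id, created_at = utc_now(),
         records = empty_audit_records()),
    class = "tgx_audit_log")
}

audit_action_kinds <- function() {
  c("rename", "merge", "replace", "delete", "reject", "stage_term",
    "vocab_merge", "issue", "issue_resolve", "session")
}

empty_audit_records <- function() {
  tibble::tibble(
    seq = integer(0), timestamp = character(0), actor = character(0),
    action_kind = character(0), dataset_id = character(0),
    target = character(0), before = character(0), after = character(0),
    justification = character(0), glp_mode = logical(0))
}

#' @export
print.tgx_audit_log <- function(x, ...) {
  cat(sprintf("<tgx_audit_log> session '%s': %d record(s)\n",
              x$session_id, nrow(x$records)))
  invisible(x)
}

blank_justification <- function(justification) {
  is.null(justification) || is.na(justification) ||
    !nzchar(trimws(justification))
}

#' Append a record to an audit log
#'
#' Assigns the next sequence number (consecutive from 1, no gaps) and the
#' current UTC timestamp. With `glp_mode = TRUE` a blank or missing
#' justification is an error and the log is unchanged.
#'
#' @param log A `tgx_audit_log`.
#' @param action_kind One of `rename`, `merge`, `replace`, `delete`,
#'   `reject`, `stage_term`, `vocab_merge`, `issue`, `issue_resolve`,
#'   `session`.
#' @param actor Who acted; defaults to the operating-system user name.
#' @param dataset_id,target,before,after Context of the action (NA where not
#'   applicable).
#' @param justification Free text; mandatory (>= 1 non-whitespace character)
#'   when `glp_mode` is TRUE, optional but recorded otherwise.
#' @param glp_mode Whether the owning session runs under GLP rules.
#' @return A new `tgx_audit_log` with the record appended.
#' @export
record <- function(log, action_kind, actor = default_actor(),
                   dataset_id = NA_character_, target = NA_character_,
                   before = NA_character_, after = NA_character_,
                   justification = NA_character_, glp_mode = FALSE) {
  if (!action_kind %in% audit_action_kinds()) {
    stop(sprintf("unknown action kind '%s'", action_kind), call. = FALSE)
  }
  if (isTRUE(glp_mode) && blank_justification(justification)) {
    stop(errorCondition(
      "GLP mode: a non-blank justification is mandatory for every action",
      class = c("tgx_glp_error", "error", "condition")))
  }
  nxt <- if (nrow(log$records) == 0L) 1L else max(log$records$seq) + 1L
  log$records <- dplyr::bind_rows(log$records, tibble::tibble(
    seq = nxt, timestamp = utc_now(), actor = actor,
    action_kind = action_kind, dataset_id = dataset_id, target = target,
    before = before, after = after,
    justification = if (is.null(justification)) NA_character_ else justification,
    glp_mode = isTRUE(glp_mode)))
  log
}

#' @rdname record
#' @export
default_actor <- function() {
  info <- Sys.info()
  actor <- unname(info[["user"]])
  if (is.null(actor) || is.na(actor) || !nzchar(actor)) "curator" else actor
}
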