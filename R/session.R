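#' Curation sessions
#'
#' A session bundles everything one curator works on: the reference and
#' temporary vocabularies, per-dataset curation states, the integration
#' result when present, and the single audit log all actions append to. GLP
#' mode is fixed at session creation and immutable afterwards — a report that
#' is partially GLP is not GLP. Sessions save to a single versioned JSON
#' document and restore to a structurally identical value.
#'
#' @param vocabulary Reference `tgx_vocabulary`.
#' @param session_id Stable identifier (kept across save/load).
#' @param glp_mode Whether every action needs a justification.
#' @param actor Default curator name.
#' @return A `tgx_session`.
#' @export
new_session <- function(vocabulary, session_id = NULL, glp_mode = FALSE,
                        actor = default_actor()) {
  session_id <- session_id %||%
    sprintf("session-%s", format(Sys.time(), "%Y%m%d%H%M%S"))
  structure(
    list(session_id = session_id, glp_mode = isTRUE(glp_mode), actor = actor,
         created_at = utc_now(), vocabulary = vocabulary,
         temp_vocab = temp_vocabulary(), curation_states = list(),
         integration = NULL, audit = audit_log(session_id)),
    class = "tgx_session")
}

session_format_version <- "1.0"

#' @export
print.tgx_session <- function(x, ...) {
  cat(sprintf("<tgx_session> '%s'%s: %d dataset(s), %d audit record(s)%s\n",
              x$session_id, if (x$glp_mode) " [GLP]" else "",
              length(x$curation_states), nrow(x$audit$records),
              if (is.null(x$integration)) "" else ", integrated"))
  invisible(x)
}

## ---- serialization -------------------------------------------------------

table_to_list <- function(t) {
  list(dataset_id = dataset_id(t),
       source_path = attr(t, "source_path", exact = TRUE),
       headers = as.list(names(t)),
       rows = lapply(seq_len(nrow(t)), function(r)
         lapply(seq_along(names(t)), function(c) t[[c]][[r]])))
}

table_from_list <- function(doc) {
  hdr <- as.character(unlist(doc$headers))
  nrows <- length(doc$rows)
  cols <- lapply(seq_along(hdr), function(c)
    vapply(seq_len(nrows), function(r) {
      cell <- doc$rows[[r]][[c]]
      if (is.null(cell)) NA_character_ else as.character(cell)
    }, character(1)))
  names(cols) <- hdr
  df <- tibble::as_tibble(cols, .name_repair = "minimal")
  sp <- doc$source_path
  metadata_table(df, dataset_id = doc$dataset_id,
                 source_path = if (is.null(sp)) NA_character_ else sp,
                 headers = hdr)
}

tibble_to_records <- function(tb) {
  lapply(seq_len(nrow(tb)), function(i) {
    row <- lapply(tb, function(col) {
      x <- col[[i]]
      if (length(x) == 1L && is.na(x)) NULL else x
    })
    row[!vapply(row, is.null, logical(1))]
  })
}

records_to_tibble <- function(recs, template) {
  if (length(recs) == 0L) return(template)
  rows <- lapply(recs, function(rec) {
    row <- template[0, ]
    vals <- lapply(names(template), function(nm) {
      x <- rec[[nm]]
      proto <- template[[nm]]
      if (is.null(x)) {
        if (is.integer(proto)) NA_integer_
        else if (is.numeric(proto)) NA_real_
        else if (is.logical(proto)) NA
        else NA_character_
      } else {
        if (is.integer(proto)) as.integer(x)
        else if (is.numeric(proto)) as.numeric(x)
        else if (is.logical(proto)) isTRUE(x)
        else as.character(x)
      }
    })
    names(vals) <- names(template)
    tibble::as_tibble(vals)
  })
  dplyr::bind_rows(rows)
}

temp_vocab_to_list <- function(t) {
  list(name = t$name, version = t$version,
       entries = tibble_to_records(t$entries))
}

temp_vocab_from_list <- function(doc) {
  t <- temp_vocabulary(name = doc$name %||% "temporary vocabulary",
                       version = as.character(doc$version %||% "1"))
  t$entries <- records_to_tibble(doc$entries, t$entries)
  t
}

#' Read and write temporary-vocabulary files
#'
#' Same JSON family as [save_vocabulary()], but each staged entry also
#' carries its `status`, `origin_dataset` and ISO-8601 `created_at`.
#'
#' @param t A `tgx_temp_vocabulary`.
#' @param path File path.
#' @export
save_temp_vocabulary <- function(t, path) {
  write_json_atomic(temp_vocab_to_list(t), path)
  invisible(path)
}

#' @rdname save_temp_vocabulary
#' @export
load_temp_vocabulary <- function(path) {
  temp_vocab_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

audit_to_list <- function(log) {
  list(session_id = log$session_id, created_at = log$created_at,
       records = tibble_to_records(log$records))
}

audit_from_list <- function(doc) {
  log <- audit_log(doc$session_id %||% "session")
  log$created_at <- doc$created_at %||% log$created_at
  log$records <- records_to_tibble(doc$records, empty_audit_records())
  log
}

curation_to_list <- function(s) {
  list(original = table_to_list(s$original),
       working = table_to_list(s$working),
       proposals = tibble_to_records(s$proposals),
       stage = s$stage, glp_mode = s$glp_mode, actor = s$actor,
       missing_tokens = as.list(s$missing_tokens),
       temp_vocab = temp_vocab_to_list(s$temp_vocab),
       audit = audit_to_list(s$audit))
}

curation_from_list <- function(doc) {
  s <- new_curation(table_from_list(doc$original),
                    glp_mode = isTRUE(doc$glp_mode), actor = doc$actor,
                    temp_vocab = temp_vocab_from_list(doc$temp_vocab),
                    audit = audit_from_list(doc$audit),
                    missing_tokens = as.character(unlist(doc$missing_tokens)))
  s$working <- table_from_list(doc$working)
  s$proposals <- records_to_tibble(doc$proposals, empty_proposals())
  s$stage <- doc$stage
  s
}

session_to_list <- function(s) {
  list(
    format_version = session_format_version,
    session_id = s$session_id, glp_mode = s$glp_mode, actor = s$actor,
    created_at = s$created_at,
    vocabulary = vocabulary_to_list(s$vocabulary),
    temp_vocab = temp_vocab_to_list(s$temp_vocab),
    curation_states = lapply(s$curation_states, curation_to_list),
    integration = if (is.null(s$integration)) NULL else list(
      table = list(
        headers = as.list(names(s$integration$table)),
        rows = lapply(seq_len(nrow(s$integration$table)), function(r)
          lapply(s$integration$table, function(col) col[[r]]))),
      report = report_to_list(s$integration$report)),
    audit = audit_to_list(s$audit))
}

session_from_list <- function(doc) {
  if (!identical(doc$format_version, session_format_version)) {
    stop(sprintf("session format version mismatch: file has '%s', this build reads '%s'",
                 doc$format_version %||% "<missing>", session_format_version),
         call. = FALSE)
  }
  s <- new_session(vocabulary_from_list(doc$vocabulary),
                   session_id = doc$session_id,
                   glp_mode = isTRUE(doc$glp_mode), actor = doc$actor)
  s$created_at <- doc$created_at
  s$temp_vocab <- temp_vocab_from_list(doc$temp_vocab)
  s$curation_states <- lapply(doc$curation_states, curation_from_list)
  if (!is.null(doc$integration)) {
    hdr <- as.character(unlist(doc$integration$table$headers))
    rows <- doc$integration$table$rows
    cols <- lapply(seq_along(hdr), function(c)
      vapply(seq_along(rows), function(r) {
        x <- rows[[r]][[c]]
        if (is.null(x)) NA_character_ else as.character(x)
      }, character(1)))
    names(cols) <- hdr
    s$integration <- list(
      table = tibble::as_tibble(cols, .name_repair = "minimal"),
      report = report_from_list(doc$integration$report))
  }
  s$audit <- audit_from_list(doc$audit)
  s
}

#' Save and restore a curation session
#'
#' The whole session — vocabularies, tables, proposals, integration result
#' and audit log — serializes to one versioned UTF-8 JSON document and
#' restores to a structurally identical session (`session_id` included). A
#' format-version mismatch is an error naming both versions.
#'
#' @param s A `tgx_session`.
#' @param path File path.
#' @return `save_session()` returns `path` invisibly; `load_session()`
#'   returns the restored `tgx_session`.
#' @export
save_session <- function(s, path) {
  write_json_atomic(session_to_list(s), path)
  invisible(path)
}

#' @rdname save_session
#' @export
load_session <- function(path) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  session_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

sessions_identical <- function(a, b) {
  identical(session_to_list(a), session_to_list(b))
}
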