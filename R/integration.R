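#' Traffic-light consistency of a feature across curated datasets
#'
#' Computes the GREEN/AMBER/RED status of one canonical feature over a set of
#' curated tables:
#' \describe{
#'   \item{GREEN}{the feature is a reference-vocabulary canonical, present in
#'     every dataset, and every observed instance resolves in the reference
#'     vocabulary;}
#'   \item{AMBER}{the only defects are terms resolvable solely via the
#'     temporary vocabulary, or absence of the feature from one or more
#'     datasets;}
#'   \item{RED}{the feature or any observed instance resolves in neither
#'     vocabulary, or two datasets map the same normalized header to
#'     different canonical features.}
#' }
#' Statuses order RED < AMBER < GREEN and the reported status is the minimum
#' over all checks, so one bad instance drags the whole feature down.
#' `reasons` enumerates every check that fired.
#'
#' @param feature Canonical feature text (as appearing as a column header).
#' @param tables List of curated `tgx_table` objects.
#' @param v Reference vocabulary.
#' @param t Temporary vocabulary (pending/approved entries count as
#'   temporary resolution).
#' @param missing_tokens Cell texts ignored as missing.
#' @return List with `status` (`"GREEN"`, `"AMBER"` or `"RED"`) and
#'   `reasons` (character vector of triggered checks; empty for GREEN).
#' @export
status_of_feature <- function(feature, tables, v, t = temp_vocabulary(),
                              missing_tokens = missing_tokens_default()) {
  reasons <- character(0)
  level <- "GREEN"
  demote <- function(lv) {
    ord <- c(RED = 1L, AMBER = 2L, GREEN = 3L)
    if (ord[[lv]] < ord[[level]]) level <<- lv
  }

  nfeat <- normalize_term(feature)
  fm <- lookup_feature(v, feature, fuzzy_threshold = 2)
  key <- fm$canonical_key
  in_ref <- fm$match_kind != "none"
  in_temp <- temp_resolves(t, feature, "feature")
  if (!in_ref && in_temp) {
    demote("AMBER")
    reasons <- c(reasons, sprintf(
      "feature '%s' resolves only via the temporary vocabulary", feature))
  }
  if (!in_ref && !in_temp) {
    demote("RED")
    reasons <- c(reasons, sprintf(
      "feature '%s' resolves in neither vocabulary", feature))
  }

  ids <- vapply(tables, dataset_id, character(1))
  present <- vapply(tables, function(tab) nfeat %in% normalize_term(names(tab)),
                    logical(1))
  for (ds in ids[!present]) {
    demote("AMBER")
    reasons <- c(reasons, sprintf("feature '%s' absent from dataset '%s'",
                                  feature, ds))
  }

  # header conflict: same normalized header, different canonical resolution
  if (in_ref) {
    mapped <- unique(unlist(lapply(tables, function(tab) {
      hdr <- names(tab)[normalize_term(names(tab)) == nfeat]
      vapply(hdr, function(h) {
        m <- lookup_feature(v, h, fuzzy_threshold = 2)
        if (m$match_kind == "none") h else m$canonical_key
      }, character(1))
    })))
    if (length(mapped) > 1L) {
      demote("RED")
      reasons <- c(reasons, sprintf(
        "datasets map normalized header '%s' to different canonical features: %s",
        nfeat, paste(sort(mapped), collapse = ", ")))
    }
  }

  for (j in which(present)) {
    tab <- tables[[j]]
    cols <- which(normalize_term(names(tab)) == nfeat)
    vals <- unique(unlist(lapply(cols, function(ci) tab[[ci]])))
    vals <- vals[!is_missing_cell(vals, missing_tokens)]
    for (val in vals) {
      ref_hit <- in_ref &&
        lookup_instance(v, key, val, fuzzy_threshold = 2)$match_kind != "none"
      temp_hit <- temp_resolves(t, val, "instance", feature_key = feature)
      if (ref_hit) next
      if (temp_hit) {
        demote("AMBER")
        reasons <- c(reasons, sprintf(
          "instance '%s' (dataset '%s') resolves only via the temporary vocabulary",
          val, ids[[j]]))
      } else {
        demote("RED")
        reasons <- c(reasons, sprintf(
          "instance '%s' (dataset '%s') resolves in neither vocabulary",
          val, ids[[j]]))
      }
    }
  }

  list(status = level, reasons = reasons)
}

#' Integrate multiple curated datasets
#'
#' Aligns two or more curated tables on the union of their features, stacks
#' all samples into one integrated table and evaluates every feature with
#' [status_of_feature()]. The output is deterministic: features sorted by
#' canonical name, rows grouped by dataset in input order, and no input cell
#' value is ever altered — a dataset lacking a feature simply contributes
#' empty cells. A `sample_id` is synthesized as `dataset_id` plus row ordinal
#' when a table has no explicit `sample_id` column.
#'
#' @param tables List of >= 2 curated `tgx_table` objects with distinct
#'   dataset identifiers.
#' @param v Reference vocabulary.
#' @param t Temporary vocabulary.
#' @param missing_tokens Cell texts ignored as missing.
#' @return List with `table` (the integrated tibble: `dataset_id`,
#'   `sample_id`, then features) and `report` (a `tgx_integration_report`).
#' @export
integrate_tables <- function(tables, v, t = temp_vocabulary(),
                             missing_tokens = missing_tokens_default()) {
  if (length(tables) < 2L) {
    stop("integration needs at least two curated tables; use single-dataset curation otherwise",
         call. = FALSE)
  }
  ids <- vapply(tables, dataset_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate dataset identifiers: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }

  # union of features by normalized header; display form = first occurrence,
  # preferring the reference-canonical spelling when known
  all_hdr <- unlist(lapply(tables, names))
  nh <- normalize_term(all_hdr)
  feats <- all_hdr[!duplicated(nh)]
  feats <- vapply(feats, function(h) {
    k <- canonical_feature_of(v, h)
    if (is.na(k)) h else k
  }, character(1), USE.NAMES = FALSE)
  feats <- setdiff(feats, feats[normalize_term(feats) == "sample id"])
  feats <- feats[order(feats)]

  blocks <- lapply(tables, function(tab) {
    n <- nrow(tab)
    sid_col <- which(normalize_term(names(tab)) == "sample id")
    sid <- if (length(sid_col) >= 1L) as.character(tab[[sid_col[[1]]]])
           else paste0(dataset_id(tab), "_", seq_len(n))
    cols <- lapply(feats, function(f) {
      ci <- which(normalize_term(names(tab)) == normalize_term(f))
      if (length(ci) == 0L) rep("", n) else as.character(tab[[ci[[1]]]])
    })
    names(cols) <- feats
    dplyr::bind_cols(
      tibble::tibble(dataset_id = rep(dataset_id(tab), n), sample_id = sid),
      tibble::as_tibble(cols))
  })
  integrated <- dplyr::bind_rows(blocks)

  rows <- lapply(feats, function(f) {
    st <- status_of_feature(f, tables, v, t, missing_tokens)
    pres <- vapply(tables, function(tab)
      normalize_term(f) %in% normalize_term(names(tab)), logical(1))
    names(pres) <- ids
    tibble::tibble(feature = f, presence = list(pres),
                   status = st$status, reasons = list(st$reasons))
  })
  report <- structure(
    list(datasets = ids,
         feature_rows = if (length(rows) > 0) dplyr::bind_rows(rows)
                        else tibble::tibble(feature = character(0),
                                            presence = list(),
                                            status = character(0),
                                            reasons = list()),
         issues = empty_issues(),
         generated_at = utc_now()),
    class = "tgx_integration_report")
  list(table = integrated, report = report)
}

empty_issues <- function() {
  tibble::tibble(feature = character(0), instance = character(0),
                 note = character(0), raised_by = character(0),
                 raised_at = character(0), resolved = logical(0))
}

#' @export
print.tgx_integration_report <- function(x, ...) {
  tab <- table(factor(x$feature_rows$status, levels = c("GREEN", "AMBER", "RED")))
  cat(sprintf("<tgx_integration_report> %d dataset(s), %d feature(s): %d GREEN, %d AMBER, %d RED; %d issue(s)\n",
              length(x$datasets), nrow(x$feature_rows),
              tab[["GREEN"]], tab[["AMBER"]], tab[["RED"]], nrow(x$issues)))
  invisible(x)
}

#' Flag a discrepancy as an Issue
#'
#' Issues mark discrepancies the curator defers to a successive curation
#' round. Marking the same target twice keeps both flags — the history is
#' preserved. Issue marking and resolution are audited when a log is
#' supplied via the session-level helpers.
#'
#' @param r A `tgx_integration_report`.
#' @param feature Canonical feature the issue concerns (must appear in the
#'   report).
#' @param instance Optional instance value within the feature.
#' @param note Non-empty description of the discrepancy.
#' @param actor Who raised the flag.
#' @return The report with the new `IssueFlag` appended.
#' @export
mark_issue <- function(r, feature, instance = NA_character_, note,
                       actor = default_actor()) {
  if (missing(note) || is.na(note) || !nzchar(trimws(note))) {
    stop("an issue needs a non-empty note", call. = FALSE)
  }
  if (!feature %in% r$feature_rows$feature) {
    stop(sprintf("feature '%s' does not appear in the report", feature),
         call. = FALSE)
  }
  r$issues <- dplyr::bind_rows(r$issues, tibble::tibble(
    feature = feature, instance = instance, note = note, raised_by = actor,
    raised_at = utc_now(), resolved = FALSE))
  r
}

#' @rdname mark_issue
#' @param index Row index of the issue to resolve (as in `r$issues`).
#' @export
resolve_issue <- function(r, index) {
  if (index < 1L || index > nrow(r$issues)) {
    stop("no such issue", call. = FALSE)
  }
  r$issues$resolved[[index]] <- TRUE
  r
}

#' Turn unresolved issues into tasks for the next curation round
#'
#' @param r A `tgx_integration_report`.
#' @return Tibble of curation tasks: one row per (dataset, feature,
#'   instance) for every unresolved issue, restricted to datasets where the
#'   feature is present.
#' @export
issues_for_next_round <- function(r) {
  open <- r$issues[!r$issues$resolved, , drop = FALSE]
  if (nrow(open) == 0L) {
    return(tibble::tibble(dataset_id = character(0), feature = character(0),
                          instance = character(0), note = character(0)))
  }
  rows <- lapply(seq_len(nrow(open)), function(i) {
    f <- open$feature[[i]]
    pres <- r$feature_rows$presence[[match(f, r$feature_rows$feature)]]
    ds <- names(pres)[pres]
    if (length(ds) == 0L) ds <- r$datasets
    tibble::tibble(dataset_id = ds, feature = f,
                   instance = open$instance[[i]], note = open$note[[i]])
  })
  dplyr::bind_rows(rows)
}

#' Export / import an integration report
#'
#' The machine format is JSON and round-trips losslessly (up to nothing: the
#' timestamp travels too). The human format is a Markdown table using the
#' literal words GREEN/AMBER/RED — plain words diff better than colour
#' codes — with one row per feature plus an issue list.
#'
#' @param r A `tgx_integration_report`.
#' @param path Output path.
#' @param format `"machine"` (JSON) or `"human"` (Markdown).
#' @return `path` invisibly; `import_report()` returns the report.
#' @export
export_report <- function(r, path, format = c("machine", "human")) {
  format <- match.arg(format)
  if (format == "machine") {
    write_json_atomic(report_to_list(r), path)
    return(invisible(path))
  }
  lines <- c(
    "# Integration report",
    "",
    sprintf("Datasets: %s", paste(r$datasets, collapse = ", ")),
    sprintf("Generated: %s", r$generated_at),
    "",
    "| feature | status | present in | reasons |",
    "| --- | --- | --- | --- |")
  for (i in seq_len(nrow(r$feature_rows))) {
    row <- r$feature_rows[i, ]
    pres <- row$presence[[1]]
    lines <- c(lines, sprintf(
      "| %s | %s | %s | %s |",
      row$feature, row$status,
      paste(names(pres)[pres], collapse = ", "),
      paste(row$reasons[[1]], collapse = "; ")))
  }
  if (nrow(r$issues) > 0L) {
    lines <- c(lines, "", "## Issues", "")
    for (i in seq_len(nrow(r$issues))) {
      is <- r$issues[i, ]
      lines <- c(lines, sprintf(
        "- [%s] %s%s: %s (raised by %s)",
        if (is$resolved) "resolved" else "open", is$feature,
        if (is.na(is$instance)) "" else paste0(" / ", is$instance),
        is$note, is$raised_by))
    }
  }
  tmp <- paste0(path, ".tmp", Sys.getpid())
  writeLines(lines, tmp, useBytes = TRUE)
  if (!file.rename(tmp, path)) { file.copy(tmp, path, overwrite = TRUE); unlink(tmp) }
  invisible(path)
}

report_to_list <- function(r) {
  list(
    datasets = as.list(unname(r$datasets)),
    generated_at = r$generated_at,
    features = lapply(seq_len(nrow(r$feature_rows)), function(i) {
      row <- r$feature_rows[i, ]
      list(feature = row$feature, status = row$status,
           presence = as.list(row$presence[[1]]),
           reasons = as.list(row$reasons[[1]]))
    }),
    issues = lapply(seq_len(nrow(r$issues)), function(i) {
      as.list(r$issues[i, ])
    }))
}

report_from_list <- function(doc) {
  feats <- doc$features
  rows <- lapply(feats, function(f) {
    pres <- vapply(f$presence, isTRUE, logical(1))
    tibble::tibble(feature = f$feature, presence = list(pres),
                   status = f$status,
                   reasons = list(as.character(unlist(f$reasons))))
  })
  issues <- if (length(doc$issues) == 0L) empty_issues() else
    dplyr::bind_rows(lapply(doc$issues, function(i) {
      tibble::tibble(feature = i$feature,
                     instance = if (is.null(i$instance)) NA_character_ else i$instance,
                     note = i$note, raised_by = i$raised_by,
                     raised_at = i$raised_at, resolved = isTRUE(i$resolved))
    }))
  structure(
    list(datasets = as.character(unlist(doc$datasets)),
         feature_rows = if (length(rows) > 0) dplyr::bind_rows(rows)
                        else tibble::tibble(feature = character(0),
                                            presence = list(),
                                            status = character(0),
                                            reasons = list()),
         issues = issues,
         generated_at = doc$generated_at),
    class = "tgx_integration_report")
}

#' @rdname export_report
#' @export
import_report <- function(path) {
  report_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

# structural equality of reports, timestamps excluded
reports_identical <- function(a, b) {
  strip <- function(r) { l <- report_to_list(r); l$generated_at <- NULL; l }
  identical(strip(a), strip(b))
}
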