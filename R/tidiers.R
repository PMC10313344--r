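#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a vocabulary into one row per term
#'
#' @param x A `tgx_vocabulary`.
#' @param ... Unused.
#' @return Tibble with columns `feature`, `level` (`feature`/`instance`),
#'   `canonical`, `term`, `is_synonym`.
#' @method tidy tgx_vocabulary
#' @export
tidy.tgx_vocabulary <- function(x, ...) {
  rows <- lapply(x$features, function(f) {
    feat <- dplyr::bind_rows(
      tibble::tibble(feature = f$canonical_name, level = "feature",
                     canonical = f$canonical_name, term = f$canonical_name,
                     is_synonym = FALSE),
      if (length(f$synonyms) > 0)
        tibble::tibble(feature = f$canonical_name, level = "feature",
                       canonical = f$canonical_name, term = f$synonyms,
                       is_synonym = TRUE))
    inst <- lapply(names(f$instances), function(ci) dplyr::bind_rows(
      tibble::tibble(feature = f$canonical_name, level = "instance",
                     canonical = ci, term = ci, is_synonym = FALSE),
      if (length(f$instances[[ci]]) > 0)
        tibble::tibble(feature = f$canonical_name, level = "instance",
                       canonical = ci, term = f$instances[[ci]],
                       is_synonym = TRUE)))
    dplyr::bind_rows(feat, dplyr::bind_rows(inst))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(feature = character(0), level = character(0),
                          canonical = character(0), term = character(0),
                          is_synonym = logical(0))
  }
  out
}

#' @rdname tidy.tgx_vocabulary
#' @method glance tgx_vocabulary
#' @export
glance.tgx_vocabulary <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    name = x$name, version = x$version,
    n_features = length(x$features),
    n_instances = sum(td$level == "instance" & !td$is_synonym),
    n_synonyms = sum(td$is_synonym))
}

#' Tidy a curation state into its proposal table
#'
#' @param x A `tgx_curation`.
#' @param ... Unused.
#' @return The proposals tibble (one row per proposal).
#' @method tidy tgx_curation
#' @export
tidy.tgx_curation <- function(x, ...) x$proposals

#' @rdname tidy.tgx_curation
#' @method glance tgx_curation
#' @export
glance.tgx_curation <- function(x, ...) {
  p <- x$proposals
  tibble::tibble(
    dataset_id = dataset_id(x$original), stage = x$stage,
    glp_mode = x$glp_mode,
    n_proposals = nrow(p),
    n_pending = sum(p$status == "pending"),
    n_accepted = sum(p$status == "accepted"),
    n_rejected = sum(p$status == "rejected"),
    n_edited = sum(p$status == "edited"),
    n_audit_records = nrow(x$audit$records))
}

#' Tidy an integration report into one row per feature
#'
#' @param x A `tgx_integration_report`.
#' @param ... Unused.
#' @return Tibble with `feature`, `status`, `n_datasets_present`,
#'   `n_reasons`, `reasons` (collapsed text).
#' @method tidy tgx_integration_report
#' @export
tidy.tgx_integration_report <- function(x, ...) {
  fr <- x$feature_rows
  tibble::tibble(
    feature = fr$feature, status = fr$status,
    n_datasets_present = vapply(fr$presence, sum, integer(1)),
    n_reasons = vapply(fr$reasons, length, integer(1)),
    reasons = vapply(fr$reasons, paste, character(1), collapse = "; "))
}

#' @rdname tidy.tgx_integration_report
#' @method glance tgx_integration_report
#' @export
glance.tgx_integration_report <- function(x, ...) {
  st <- factor(x$feature_rows$status, levels = c("GREEN", "AMBER", "RED"))
  tab <- table(st)
  tibble::tibble(
    n_datasets = length(x$datasets), n_features = nrow(x$feature_rows),
    n_green = as.integer(tab[["GREEN"]]), n_amber = as.integer(tab[["AMBER"]]),
    n_red = as.integer(tab[["RED"]]),
    n_open_issues = sum(!x$issues$resolved))
}

#' Tidy an audit log into its record table
#'
#' @param x A `tgx_audit_log`.
#' @param ... Unused.
#' @return The records tibble, ordered by `seq`.
#' @method tidy tgx_audit_log
#' @export
tidy.tgx_audit_log <- function(x, ...) {
  x$records[order(x$records$seq), , drop = FALSE]
}

#' @rdname tidy.tgx_audit_log
#' @method glance tgx_audit_log
#' @export
glance.tgx_audit_log <- function(x, ...) {
  r <- x$records
  tibble::tibble(
    session_id = x$session_id, n_records = nrow(r),
    n_data_changes = sum(r$action_kind %in%
                           c("rename", "merge", "replace", "delete")),
    n_rejections = sum(r$action_kind == "reject"),
    n_glp = sum(r$glp_mode))
}

#' Tidy a temporary vocabulary into its staged entries
#'
#' @param x A `tgx_temp_vocabulary`.
#' @param ... Unused.
#' @return The entries tibble.
#' @method tidy tgx_temp_vocabulary
#' @export
tidy.tgx_temp_vocabulary <- function(x, ...) x$entries
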