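#' Read a batch decision file
#'
#' A decision file stands in for the interactive user: a JSON list of
#' objects `{"proposal_id", "decision": "accept"|"reject"|"edit",
#' "edited_value"?, "justification"?}`. Duplicate-column groups are decided
#' under the identifier `dedup:<normalized header>` (`accept` merges with
#' first-non-missing-wins, `reject` keeps all columns, `edit` keeps the
#' column position given in `edited_value`).
#'
#' @param path JSON file path.
#' @return Tibble with columns `proposal_id`, `decision`, `edited_value`,
#'   `justification`.
#' @export
read_decisions <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (length(doc) == 0L) {
    return(tibble::tibble(proposal_id = character(0), decision = character(0),
                          edited_value = character(0),
                          justification = character(0)))
  }
  dplyr::bind_rows(lapply(doc, function(d) tibble::tibble(
    proposal_id = d$proposal_id, decision = d$decision,
    edited_value = d$edited_value %||% NA_character_,
    justification = d$justification %||% NA_character_)))
}

decision_for <- function(decisions, id) {
  if (is.null(decisions) || nrow(decisions) == 0L) return(NULL)
  hit <- which(decisions$proposal_id == id)
  if (length(hit) == 0L) return(NULL)
  as.list(decisions[hit[[1]], ])
}

#' Curate one table end to end with scripted decisions
#'
#' Drives the full three-stage pipeline without a human at the keyboard.
#' Each generated proposal is decided by, in order of precedence: an entry
#' in the `decisions` table; the `auto_accept_exact` policy (accepting only
#' exact/normalized hits — fuzzy and unmatched proposals are never
#' auto-applied); otherwise rejection with `default_justification`.
#' Duplicate-column groups without an explicit decision are merged
#' first-non-missing-wins when safe and kept intact otherwise. Terms the
#' vocabulary could not resolve are staged into the temporary vocabulary
#' (audited), ready for review and promotion.
#'
#' @param table A `tgx_table`.
#' @param v Reference vocabulary.
#' @param decisions Optional tibble from [read_decisions()].
#' @param auto_accept_exact Accept exact/normalized matches without an
#'   explicit decision (the scripted-run policy flag).
#' @param fuzzy_threshold Fuzzy-match threshold for proposals.
#' @param glp_mode,actor,temp_vocab,audit,missing_tokens As in
#'   [new_curation()].
#' @param default_justification Justification recorded for policy-driven
#'   decisions (GLP mode needs one on every action).
#' @return The finished `tgx_curation` state (stage `done`).
#' @export
curate_auto <- function(table, v, decisions = NULL, auto_accept_exact = TRUE,
                        fuzzy_threshold = 0.85, glp_mode = FALSE,
                        actor = default_actor(), temp_vocab = NULL,
                        audit = NULL,
                        missing_tokens = missing_tokens_default(),
                        default_justification = "batch policy decision") {
  s <- new_curation(table, glp_mode = glp_mode, actor = actor,
                    temp_vocab = temp_vocab, audit = audit,
                    missing_tokens = missing_tokens)
  ds <- dataset_id(table)

  decide_all <- function(s) {
    pend <- s$proposals[s$proposals$status == "pending", , drop = FALSE]
    for (i in seq_len(nrow(pend))) {
      p <- pend[i, ]
      d <- decision_for(decisions, p$proposal_id)
      if (!is.null(d)) {
        s <- apply_decision(s, p$proposal_id, d$decision,
                            edited_value = if (is.na(d$edited_value)) NULL
                                           else d$edited_value,
                            justification = d$justification)
      } else if (auto_accept_exact &&
                 p$match_kind %in% c("exact", "normalized")) {
        s <- apply_decision(s, p$proposal_id, "accept",
                            justification = "exact vocabulary match (batch policy)")
      } else {
        s <- apply_decision(s, p$proposal_id, "reject",
                            justification = default_justification)
      }
    }
    s
  }

  # stage (i): column renaming
  s <- propose_column_renames(s, v, fuzzy_threshold)
  s <- decide_all(s)
  s <- advance_stage(s)

  # stage (ii): duplicate columns; groups kept intact stay in the table, so
  # remember their headers to avoid re-resolving them forever
  kept_intact <- character(0)
  repeat {
    groups <- detect_duplicate_columns(s)
    groups <- groups[!vapply(groups, function(g) g$header %in% kept_intact,
                             logical(1))]
    if (length(groups) == 0L) break
    g <- groups[[1]]
    d <- decision_for(decisions, paste0("dedup:", g$header))
    if (!is.null(d)) {
      s <- switch(d$decision,
        accept = resolve_duplicates(s, g, "keep_first_fill_missing",
                                    justification = d$justification),
        reject = resolve_duplicates(s, g, "keep_all",
                                    justification = d$justification),
        edit = resolve_duplicates(s, g, "keep_named_column",
                                  keep = as.integer(d$edited_value),
                                  justification = d$justification),
        stop(sprintf("unknown dedup decision '%s'", d$decision), call. = FALSE))
      if (d$decision == "reject") kept_intact <- c(kept_intact, g$header)
    } else if (all(g$agreement)) {
      s <- resolve_duplicates(s, g, "keep_first_fill_missing",
                              justification = "duplicate columns agree cell-wise (batch policy)")
    } else {
      s <- resolve_duplicates(s, g, "keep_all",
                              justification = "conflicting duplicate columns kept for review (batch policy)")
      kept_intact <- c(kept_intact, g$header)
    }
  }
  s <- advance_stage(s)

  # stage (iii): value harmonization for every canonical column
  for (ci in seq_along(names(s$working))) {
    if (!is.na(canonical_feature_of(v, names(s$working)[[ci]]))) {
      s <- propose_value_harmonization(s, ci, v, fuzzy_threshold)
    }
  }
  s <- decide_all(s)

  # stage unresolved terms into the temporary vocabulary
  um <- unmatched_terms(s)
  for (i in seq_len(nrow(um))) {
    as_kind <- if (um$kind[[i]] == "rename_column") "feature" else "instance"
    fk <- if (as_kind == "instance")
      canonical_feature_of(v, um$column[[i]]) else NA_character_
    if (as_kind == "instance" && is.na(fk)) next
    id <- temp_entry_id(fk, um$term[[i]], as_kind)
    if (id %in% s$temp_vocab$entries$entry_id) next
    staged <- tryCatch(
      stage_term(s$temp_vocab, v, feature_key = fk, term = um$term[[i]],
                 as_kind = as_kind, origin_dataset = ds),
      error = function(e) NULL)
    if (is.null(staged)) next
    s$audit <- record(s$audit, "stage_term", actor = s$actor,
                      dataset_id = ds,
                      target = paste0(as_kind, ":", normalize_term(um$term[[i]])),
                      before = um$term[[i]], after = fk,
                      justification = "unresolved term staged for vocabulary review",
                      glp_mode = s$glp_mode)
    s$temp_vocab <- staged
  }

  advance_stage(s)
}

classify_exit <- function(e) {
  if (inherits(e, "tgx_glp_error")) 4L
  else if (inherits(e, "tgx_vocab_error")) 3L
  else 2L
}

as_vocabulary <- function(v) {
  if (inherits(v, "tgx_vocabulary")) v else load_vocabulary(v)
}

#' Run single-dataset curation mode
#'
#' Loads the inputs, curates each table through [curate_auto()] inside one
#' session, and writes all artifacts: the curated tables, the temporary
#' vocabulary, the saved session, and the human-readable report. In GLP mode
#' with a decision file, every decision must already carry a justification —
#' validated before any action runs, so a bad file changes nothing.
#'
#' @param inputs Character vector of table paths, or a list of `tgx_table`
#'   objects.
#' @param vocabulary A `tgx_vocabulary` or path to one.
#' @param output_dir Directory for artifacts (created if needed).
#' @param decisions Path to a decision file, or a tibble from
#'   [read_decisions()], or NULL.
#' @param glp_mode,actor,fuzzy_threshold,auto_accept_exact See
#'   [curate_auto()].
#' @param session_id Stable session identifier.
#' @return List with `status` (0 success; 2 input/format error; 3 vocabulary
#'   validation error; 4 GLP violation), `session`, `curated` (list of
#'   tables) and `paths`; on failure `error` holds the message.
#' @export
run_single <- function(inputs, vocabulary, output_dir = tempfile("curation"),
                       decisions = NULL, glp_mode = FALSE,
                       actor = default_actor(), fuzzy_threshold = 0.85,
                       auto_accept_exact = TRUE, session_id = NULL) {
  tryCatch({
    v <- as_vocabulary(vocabulary)
    dec <- if (is.character(decisions)) read_decisions(decisions) else decisions
    if (glp_mode && !is.null(dec) && nrow(dec) > 0L) {
      blank <- vapply(dec$justification, blank_justification, logical(1))
      if (any(blank)) {
        stop(errorCondition(
          paste0("GLP mode: decision(s) without justification: ",
                 paste(dec$proposal_id[blank], collapse = ", ")),
          class = c("tgx_glp_error", "error", "condition")))
      }
    }
    tables <- if (is.character(inputs)) lapply(inputs, load_table) else inputs

    ses <- new_session(v, session_id = session_id, glp_mode = glp_mode,
                       actor = actor)
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list()
    curated <- list()
    for (t in tables) {
      st <- curate_auto(t, v, decisions = dec,
                        auto_accept_exact = auto_accept_exact,
                        fuzzy_threshold = fuzzy_threshold,
                        glp_mode = glp_mode, actor = actor,
                        temp_vocab = ses$temp_vocab, audit = ses$audit)
      ses$curation_states[[dataset_id(t)]] <- st
      ses$temp_vocab <- st$temp_vocab
      ses$audit <- st$audit
      out <- curated_table(st)
      curated[[dataset_id(t)]] <- out
      p <- file.path(output_dir, paste0(dataset_id(t), "_curated.csv"))
      write_table(out, p)
      paths[[paste0("curated_", dataset_id(t))]] <- p
    }
    paths$temp_vocabulary <- file.path(output_dir, "temp_vocabulary.json")
    save_temp_vocabulary(ses$temp_vocab, paths$temp_vocabulary)
    paths$session <- file.path(output_dir, "session.json")
    save_session(ses, paths$session)
    paths$report <- file.path(output_dir, "report.md")
    generate_report(ses, "human", paths$report)
    list(status = 0L, session = ses, curated = curated, paths = paths)
  }, error = function(e) {
    list(status = classify_exit(e), error = conditionMessage(e))
  })
}

#' Run multiple-dataset integration mode
#'
#' Integrates curated tables (given directly, as paths, or from a session's
#' finished curation states), writes the integrated table plus machine and
#' human integration reports, and persists the result in the session. RED
#' statuses are findings, not failures: the run still exits 0.
#'
#' @param inputs Curated tables (paths or `tgx_table`s), or NULL to take
#'   every finished dataset from `session`.
#' @param vocabulary A `tgx_vocabulary` or path (ignored when a session is
#'   given).
#' @param session A `tgx_session` or path to one, or NULL.
#' @param output_dir Artifact directory.
#' @return List with `status`, `integrated`, `report`, `session`, `paths`.
#' @export
run_multi <- function(inputs = NULL, vocabulary = NULL, session = NULL,
                      output_dir = tempfile("integration")) {
  tryCatch({
    ses <- if (is.character(session)) load_session(session) else session
    if (is.null(ses)) {
      v <- as_vocabulary(vocabulary)
      ses <- new_session(v)
    }
    v <- ses$vocabulary
    if (is.null(inputs)) {
      unfinished <- names(ses$curation_states)[
        !vapply(ses$curation_states, function(s) identical(s$stage, "done"),
                logical(1))]
      if (length(unfinished) > 0L) {
        stop(sprintf("dataset(s) not fully curated: %s; finish single-dataset mode first",
                     paste(unfinished, collapse = ", ")), call. = FALSE)
      }
      tables <- lapply(ses$curation_states, curated_table)
    } else {
      tables <- if (is.character(inputs)) lapply(inputs, load_table) else inputs
    }
    out <- integrate_tables(tables, v, ses$temp_vocab)
    ses$integration <- out
    ses$audit <- record(ses$audit, "session", actor = ses$actor,
                        target = "integration",
                        after = sprintf("%d datasets, %d features",
                                        length(out$report$datasets),
                                        nrow(out$report$feature_rows)),
                        justification = "multiple-dataset integration executed",
                        glp_mode = ses$glp_mode)
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(
      integrated = file.path(output_dir, "integrated.csv"),
      report_json = file.path(output_dir, "integration_report.json"),
      report_md = file.path(output_dir, "integration_report.md"),
      session = file.path(output_dir, "session.json"))
    readr::write_csv(out$table, paths$integrated, na = "")
    export_report(out$report, paths$report_json, "machine")
    export_report(out$report, paths$report_md, "human")
    save_session(ses, paths$session)
    list(status = 0L, integrated = out$table, report = out$report,
         session = ses, paths = paths)
  }, error = function(e) {
    list(status = classify_exit(e), error = conditionMessage(e))
  })
}

#' Verify a session by replaying its audit log
#'
#' Reconstructs the curated tables from the session's original tables and
#' starting vocabulary via [replay()] and compares them structurally to the
#' session's stored working tables. Exit status 0 means fully reproducible;
#' 5 reports the first divergence.
#'
#' @param session A `tgx_session` or path to a saved one.
#' @return List with `status` (0 identical, 5 divergence, 2 input error) and
#'   `divergence` (message) when statuses differ.
#' @export
run_replay <- function(session) {
  tryCatch({
    ses <- if (is.character(session)) load_session(session) else session
    originals <- lapply(ses$curation_states, function(s) s$original)
    rep <- replay(unname(originals), ses$vocabulary, ses$audit)
    for (ds in names(ses$curation_states)) {
      live <- ses$curation_states[[ds]]$working
      got <- rep$tables[[ds]]
      if (is.null(got) || !tables_identical(live, got)) {
        return(list(status = 5L, divergence = sprintf(
          "dataset '%s': replayed table differs from the stored curated table",
          ds)))
      }
    }
    list(status = 0L, tables = rep$tables, vocabulary = rep$vocabulary,
         temp_vocab = rep$temp_vocab)
  }, error = function(e) {
    st <- if (grepl("^replay failed", conditionMessage(e))) 5L else
      classify_exit(e)
    list(status = st, divergence = conditionMessage(e))
  })
}

#' Write the session report
#'
#' @param session A `tgx_session` or path.
#' @param path Output file.
#' @param format `"human"` (Markdown) or `"machine"` (JSON).
#' @return List with `status` and `path`.
#' @export
run_report <- function(session, path, format = c("human", "machine")) {
  tryCatch({
    ses <- if (is.character(session)) load_session(session) else session
    generate_report(ses, match.arg(format), path)
    list(status = 0L, path = path)
  }, error = function(e) list(status = classify_exit(e),
                              error = conditionMessage(e)))
}

#' Generate fixture artifacts on disk
#'
#' @param spec A [fixture_spec()] or path to a JSON spec.
#' @param output_dir Directory receiving `vocabulary.json`, messy tables
#'   (`<dataset>.csv`), ground-truth tables (`<dataset>_truth.csv`) and the
#'   corruption mapping (`mapping.csv`).
#' @return List with `status`, `fixture`, `paths`.
#' @export
run_fixture <- function(spec, output_dir = tempfile("fixture")) {
  tryCatch({
    if (is.character(spec)) spec <- load_fixture_spec(spec)
    fx <- make_fixture(spec)
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(vocabulary = file.path(output_dir, "vocabulary.json"))
    save_vocabulary(fx$vocabulary, paths$vocabulary)
    for (i in seq_along(fx$messy)) {
      ds <- dataset_id(fx$messy[[i]])
      paths[[ds]] <- file.path(output_dir, paste0(ds, ".csv"))
      write_table(fx$messy[[i]], paths[[ds]])
      paths[[paste0(ds, "_truth")]] <-
        file.path(output_dir, paste0(ds, "_truth.csv"))
      write_table(fx$truth[[i]], paths[[paste0(ds, "_truth")]])
    }
    paths$mapping <- file.path(output_dir, "mapping.csv")
    readr::write_csv(fx$mapping, paths$mapping, na = "")
    list(status = 0L, fixture = fx, paths = paths)
  }, error = function(e) list(status = classify_exit(e),
                              error = conditionMessage(e)))
}
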