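test_that("delimited tables load rectangularly with verbatim cells", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1, x", "2,y", "3,z"), p)
  t <- load_table(p)
  expect_s3_class(t, "tgx_table")
  expect_identical(names(t), c("a", "b"))
  expect_identical(nrow(t), 3L)
  expect_identical(t$b[[1]], " x")  # no trimming at load
  expect_identical(dataset_id(t), sub("\\.csv$", "", basename(p)))
})

test_that("ragged rows are an error naming the first bad row", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("a,b", "1,2", "3"), p)
  expect_error(load_table(p), "row 3")  # physical file line of the bad row
})

test_that("duplicate headers load; blank headers do not", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("race,race", "B,C"), p)
  t <- load_table(p)
  expect_identical(names(t), c("race", "race"))
  writeLines(c("a,", "1,2"), p)
  expect_error(load_table(p), "blank")
})

test_that("write/load round-trips random tables including duplicates and quoting", {
  p <- withr::local_tempfile(fileext = ".csv")
  set.seed(5)
  for (i in 1:30) {
    ncol <- sample(2:5, 1)
    hdr <- c("dup", "dup", vapply(seq_len(ncol - 2), function(j)
      paste0(sample(letters, 4), collapse = ""), character(1)))[seq_len(ncol)]
    cells <- matrix(sample(c("plain", "with,comma", "with \"quote\"",
                             "two words", "NA", ""), ncol * 4, TRUE),
                    nrow = 4)
    t <- metadata_table(as.data.frame(cells), dataset_id = "ds",
                        headers = hdr)
    write_table(t, p)
    t2 <- load_table(p, dataset_id = "ds")
    expect_tables_equal(t, t2)
  }
})

test_that("header renaming proposes canonical features in column order", {
  v <- ethnicity_vocabulary()
  t <- metadata_table(tibble::tibble(a = "x", b = "y", c = "z"),
                      dataset_id = "d",
                      headers = c("race", "ethnicity", "age"))
  s <- propose_column_renames(new_curation(t), v)
  p <- tidy(s)
  expect_identical(nrow(p), 3L)
  expect_identical(p$col_index, 1:3)
  expect_identical(p$suggested[1:2], c("ethnicity", "ethnicity"))
  expect_identical(p$match_kind, c("exact", "exact", "none"))
  expect_true(is.na(p$suggested[[3]]))
  # the already-canonical header is an auto-acceptable no-op
  expect_identical(p$current[[2]], p$suggested[[2]])
})

test_that("fuzzy header proposals carry the brute-force top candidate", {
  v <- ethnicity_vocabulary()
  t <- metadata_table(tibble::tibble(x = "y"), "d", headers = "Ethncity")
  s <- propose_column_renames(new_curation(t), v, fuzzy_threshold = 0.8)
  p <- tidy(s)
  expect_identical(p$match_kind, "fuzzy")
  want <- oracle_feature_ranking(v, "Ethncity", 0.8)
  expect_identical(p$suggested, names(want)[[1]])
})

test_that("duplicate detection groups normalized headers and summarises agreement", {
  t <- metadata_table(
    tibble::tibble(a = c("B", "C", ""), b = c("B", "", "NA"),
                   c = c("1", "2", "3")),
    "d", headers = c("ethnicity", "Ethnicity", "age"))
  s <- new_curation(t)
  s$stage <- "dedup"
  g <- detect_duplicate_columns(s)
  expect_length(g, 1)
  expect_identical(g[[1]]$positions, 1:2)
  expect_identical(g[[1]]$agreement, c(TRUE, TRUE, TRUE))

  t2 <- metadata_table(tibble::tibble(a = "1", b = "2"), "d",
                       headers = c("x", "y"))
  s2 <- new_curation(t2); s2$stage <- "dedup"
  expect_length(detect_duplicate_columns(s2), 0)
})

test_that("agreement summaries equal a brute-force all-pairs scan on random tables", {
  set.seed(31)
  for (i in 1:40) {
    nr <- sample(3:10, 1)
    vals <- sample(c("a", "b", "", "NA"), nr * 2, replace = TRUE)
    t <- metadata_table(as.data.frame(matrix(vals, nrow = nr)), "d",
                        headers = c("h", "h"))
    s <- new_curation(t); s$stage <- "dedup"
    got <- detect_duplicate_columns(s)[[1]]$agreement
    want <- vapply(seq_len(nr), function(r) {
      cells <- c(t[[1]][[r]], t[[2]][[r]])
      cells <- cells[!cells %in% c("", "NA")]
      length(unique(cells)) <= 1L
    }, logical(1))
    expect_identical(got, want)
  }
})

test_that("merging duplicates coalesces first-non-missing and audits; conflicts block", {
  t <- metadata_table(
    tibble::tibble(a = c("", "C", ""), b = c("B", "", "-")),
    "d", headers = c("ethnicity", "ethnicity"))
  s <- new_curation(t); s$stage <- "dedup"
  g <- detect_duplicate_columns(s)[[1]]
  s2 <- resolve_duplicates(s, g, "keep_first_fill_missing")
  expect_identical(names(s2$working), "ethnicity")
  expect_identical(as.character(s2$working[[1]]), c("B", "C", ""))
  expect_identical(s2$audit$records$action_kind, "merge")

  tc <- metadata_table(tibble::tibble(a = c("B", "C"), b = c("W", "C")),
                       "d", headers = c("ethnicity", "ethnicity"))
  sc <- new_curation(tc); sc$stage <- "dedup"
  gc <- detect_duplicate_columns(sc)[[1]]
  expect_error(resolve_duplicates(sc, gc, "keep_first_fill_missing"),
               "row\\(s\\) 1")
})

test_that("keep_all leaves the table unchanged but is audited", {
  t <- metadata_table(tibble::tibble(a = "B", b = "C"), "d",
                      headers = c("ethnicity", "ethnicity"))
  s <- new_curation(t); s$stage <- "dedup"
  g <- detect_duplicate_columns(s)[[1]]
  s2 <- resolve_duplicates(s, g, "keep_all")
  expect_tables_equal(s2$working, t)
  expect_identical(nrow(s2$audit$records), 1L)
})

test_that("merging a column that is all-missing yields the other column", {
  t <- metadata_table(tibble::tibble(a = c("B", "C"), b = c("", "NA")),
                      "d", headers = c("ethnicity", "ethnicity"))
  s <- new_curation(t); s$stage <- "dedup"
  s2 <- resolve_duplicates(s, detect_duplicate_columns(s)[[1]],
                           "keep_first_fill_missing")
  expect_identical(as.character(s2$working[[1]]), c("B", "C"))
})

test_that("random duplicate merges equal a brute-force cell-wise coalesce", {
  set.seed(63)
  for (i in 1:40) {
    nr <- sample(2:8, 1)
    a <- sample(c("x", "", "NA"), nr, TRUE)
    b <- ifelse(a == "x", sample(c("x", ""), nr, TRUE),
                sample(c("y", "", "-"), nr, TRUE))
    t <- metadata_table(tibble::tibble(a = a, b = b), "d",
                        headers = c("h", "h"))
    s <- new_curation(t); s$stage <- "dedup"
    g <- detect_duplicate_columns(s)[[1]]
    conflict <- any(!g$agreement)
    if (conflict) {
      expect_error(resolve_duplicates(s, g, "keep_first_fill_missing"))
    } else {
      merged <- resolve_duplicates(s, g, "keep_first_fill_missing")$working[[1]]
      want <- vapply(seq_len(nr), function(r) {
        cells <- c(a[[r]], b[[r]])
        nm <- cells[!cells %in% c("", "NA", "-")]
        if (length(nm) == 0L) cells[[1]] else nm[[1]]
      }, character(1))
      expect_identical(as.character(merged), want)
    }
  }
})

test_that("value harmonization proposes one proposal per unique value only", {
  v <- ethnicity_vocabulary()
  vals <- sample(c("Caucasian", "B", "Inuit"), 1000, replace = TRUE)
  t <- metadata_table(tibble::tibble(x = vals), "d", headers = "ethnicity")
  s <- new_curation(t); s$stage <- "values"
  s <- propose_value_harmonization(s, 1, v)
  expect_identical(nrow(s$proposals), 3L)
  p <- s$proposals
  expect_setequal(p$suggested, c("White", "Black", "Inuit"))
  expect_true(all(p$kind == "replace_value"))
})

test_that("harmonizing a non-canonical column directs back to renaming", {
  v <- ethnicity_vocabulary()
  t <- metadata_table(tibble::tibble(x = "B"), "d", headers = "race")
  s <- new_curation(t); s$stage <- "values"
  expect_error(propose_value_harmonization(s, 1, v), "stage \\(i\\)")
})

test_that("accepting a replacement rewrites all equal cells and audits once", {
  v <- ethnicity_vocabulary()
  t <- metadata_table(tibble::tibble(x = c("B", "Inuit", "B")), "d",
                      headers = "ethnicity")
  s <- new_curation(t); s$stage <- "values"
  s <- propose_value_harmonization(s, 1, v)
  id <- s$proposals$proposal_id[s$proposals$current == "B"]
  s <- apply_decision(s, id, "accept")
  expect_identical(as.character(s$working[[1]]), c("Black", "Inuit", "Black"))
  expect_identical(nrow(s$audit$records), 1L)
  expect_identical(s$audit$records$before, "B")
  expect_identical(s$audit$records$after, "Black")
})

test_that("rejection leaves data untouched but is audited", {
  v <- ethnicity_vocabulary()
  t <- ethnicity_table()
  s <- propose_column_renames(new_curation(t), v)
  s2 <- apply_decision(s, s$proposals$proposal_id[[1]], "reject")
  expect_tables_equal(s2$working, t)
  expect_identical(s2$audit$records$action_kind, "reject")
  expect_identical(s2$proposals$status[[1]], "rejected")
})

test_that("editing applies the user's value and records it", {
  v <- ethnicity_vocabulary()
  t <- metadata_table(tibble::tibble(x = "x"), "d", headers = "patient race")
  s <- propose_column_renames(new_curation(t), v)
  s <- apply_decision(s, s$proposals$proposal_id[[1]], "edit",
                      edited_value = "ethnicity")
  expect_identical(names(s$working), "ethnicity")
  expect_identical(s$proposals$status[[1]], "edited")
  expect_identical(s$proposals$edited_value[[1]], "ethnicity")
})

test_that("GLP mode rejects blank justifications with no state change", {
  v <- ethnicity_vocabulary()
  t <- ethnicity_table()
  s <- propose_column_renames(new_curation(t, glp_mode = TRUE), v)
  id <- s$proposals$proposal_id[[1]]
  for (bad in list(NULL, NA_character_, "", "   ")) {
    err <- tryCatch(apply_decision(s, id, "accept", justification = bad),
                    error = function(e) e)
    expect_s3_class(err, "tgx_glp_error")
  }
  expect_identical(nrow(s$audit$records), 0L)
  expect_tables_equal(s$working, t)
  s2 <- apply_decision(s, id, "accept", justification = "exact synonym hit")
  expect_identical(names(s2$working), "ethnicity")
})

test_that("unknown or already-decided proposals are errors", {
  v <- ethnicity_vocabulary()
  s <- propose_column_renames(new_curation(ethnicity_table()), v)
  expect_error(apply_decision(s, "nope", "accept"), "unknown proposal")
  id <- s$proposals$proposal_id[[1]]
  s <- apply_decision(s, id, "accept")
  expect_error(apply_decision(s, id, "accept"), "not pending")
})

test_that("operations of a later stage error when called early, and stages never go back", {
  v <- ethnicity_vocabulary()
  s <- new_curation(ethnicity_table())
  expect_error(detect_duplicate_columns(s), "stage")
  expect_error(propose_value_harmonization(s, 1, v), "stage")
  s$stage <- "values"
  expect_error(propose_column_renames(s, v), "stage")
})

test_that("unmatched terms are exactly the proposals the vocabulary missed", {
  v <- ethnicity_vocabulary()
  t <- metadata_table(tibble::tibble(x = c("B", "Maori")), "d",
                      headers = "ethnicity")
  s <- new_curation(t); s$stage <- "values"
  s <- propose_value_harmonization(s, 1, v)
  um <- unmatched_terms(s)
  expect_identical(um$term, "Maori")
  expect_identical(um$column, "ethnicity")

  # brute-force filter over random proposal tables
  set.seed(12)
  for (i in 1:30) {
    n <- sample(1:10, 1)
    s$proposals <- tibble::tibble(
      proposal_id = paste0("p", seq_len(n)), kind = "replace_value",
      col_index = 1L, target_column = "ethnicity",
      current = paste0("v", seq_len(n)),
      suggested = NA_character_,
      match_kind = sample(c("none", "exact", "fuzzy"), n, TRUE),
      score = 0, ambiguous = FALSE,
      status = sample(c("pending", "accepted", "rejected"), n, TRUE),
      edited_value = NA_character_)
    got <- unmatched_terms(s)$term
    want <- s$proposals$current[
      s$proposals$match_kind == "none" &
        s$proposals$status %in% c("pending", "edited", "rejected")]
    expect_identical(got, want)
  }
})

test_that("the curated table is withheld while proposals are pending", {
  v <- ethnicity_vocabulary()
  s <- propose_column_renames(new_curation(ethnicity_table()), v)
  expect_error(curated_table(s), "pending")
  s <- apply_decision(s, s$proposals$proposal_id[[1]], "accept")
  expect_error(curated_table(s), "not finished")
  s$stage <- "done"
  expect_identical(names(curated_table(s)), "ethnicity")
})

test_that("the original table is never modified by curation", {
  v <- ethnicity_vocabulary()
  t <- ethnicity_table()
  before <- list(names(t), lapply(t, as.character))
  s <- curate_auto(t, v)
  expect_identical(list(names(s$original), lapply(s$original, as.character)),
                   before)
  expect_false(identical(names(s$original), names(s$working)))
})

test_that("the demographic scenario curates to the canonical instance set", {
  v <- ethnicity_vocabulary()
  s <- curate_auto(ethnicity_table(), v)
  out <- curated_table(s)
  expect_identical(names(out), "ethnicity")
  expect_setequal(unique(out$ethnicity), c("Black", "White", "Inuit"))
  expect_identical(out$ethnicity, c("White", "Black", "Inuit", "Black", "White"))
})

test_that("re-curating a curated table proposes only no-ops", {
  v <- ethnicity_vocabulary()
  out <- curated_table(curate_auto(ethnicity_table(), v))
  s2 <- curate_auto(out, v)
  p <- tidy(s2)
  expect_true(all(p$current == p$suggested))
  expect_tables_equal(curated_table(s2), out)
})

test_that("every working/original difference is attributable to one audit record", {
  for (seed in 1:10) {
    fx <- make_fixture(fixture_spec(seed = seed,
                                    corruption = solvable_profile()))
    st <- curate_auto(fx$messy[[1]], fx$vocabulary)
    rec <- st$audit$records
    changes <- rec[rec$action_kind %in% c("rename", "merge", "replace",
                                          "delete") &
                     (is.na(rec$after) | is.na(rec$before) |
                        rec$before != rec$after), , drop = FALSE]
    # replaying only the audited actions reconstructs the working table
    rep <- replay(list(st$original), fx$vocabulary, st$audit)
    expect_tables_equal(rep$tables[[1]], st$working)
    # and a log stripped of any one change no longer does
    if (nrow(changes) > 0L) {
      drop_seq <- changes$seq[[sample(nrow(changes), 1)]]
      log2 <- st$audit
      log2$records <- log2$records[log2$records$seq != drop_seq, , drop = FALSE]
      broken <- tryCatch(replay(list(st$original), fx$vocabulary, log2),
                         error = function(e) NULL)
      expect_false(!is.null(broken) &&
                     tgxcurate:::tables_identical(broken$tables[[1]],
                                                  st$working))
    }
  }
})
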