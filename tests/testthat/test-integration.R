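two_curated_tables <- function() {
  v <- ethnicity_vocabulary()
  t1 <- metadata_table(tibble::tibble(x = c("Black", "White")), "geo1",
                       headers = "ethnicity")
  t2 <- metadata_table(tibble::tibble(x = c("Inuit", "Black")), "geo2",
                       headers = "ethnicity")
  list(v = v, tables = list(t1, t2))
}

test_that("a feature canonical everywhere with known instances is GREEN", {
  w <- two_curated_tables()
  st <- status_of_feature("ethnicity", w$tables, w$v)
  expect_identical(st$status, "GREEN")
  expect_length(st$reasons, 0)
})

test_that("absence from one dataset is AMBER with the dataset named", {
  w <- two_curated_tables()
  t2 <- metadata_table(tibble::tibble(x = "10"), "geo2", headers = "dose")
  st <- status_of_feature("ethnicity", list(w$tables[[1]], t2), w$v)
  expect_identical(st$status, "AMBER")
  expect_match(st$reasons, "absent from dataset 'geo2'", all = FALSE)
})

test_that("instances known only to the temporary vocabulary are AMBER", {
  w <- two_curated_tables()
  t1 <- metadata_table(tibble::tibble(x = c("Black", "Maori")), "geo1",
                       headers = "ethnicity")
  tv <- stage_term(temp_vocabulary(), w$v, "ethnicity", "Maori", "instance")
  st <- status_of_feature("ethnicity", list(t1, w$tables[[2]]), w$v, tv)
  expect_identical(st$status, "AMBER")
  st2 <- status_of_feature("ethnicity", list(t1, w$tables[[2]]), w$v)
  expect_identical(st2$status, "RED")
})

test_that("unknown instances or features are RED", {
  w <- two_curated_tables()
  t1 <- metadata_table(tibble::tibble(x = "Martian"), "geo1",
                       headers = "ethnicity")
  expect_identical(
    status_of_feature("ethnicity", list(t1, w$tables[[2]]), w$v)$status,
    "RED")
  expect_identical(
    status_of_feature("weight", w$tables, w$v)$status, "RED")
})

test_that("statuses equal brute-force rule evaluation on random fixtures", {
  set.seed(17)
  n_checked <- 0
  for (i in 1:25) {
    spec <- fixture_spec(
      seed = 300 + i, n_features = 3, n_datasets = 2, rows_per_dataset = 6,
      corruption = corruption_profile(p_synonym_swap = 0.3,
                                      p_case_mangle = 0.2, p_missing = 0.1,
                                      p_unknown_term = 0.15,
                                      p_duplicate_column = 0))
    fx <- make_fixture(spec)
    # drop a random column from one table to create absence defects
    tables <- fx$messy
    if (runif(1) < 0.5 && ncol(tables[[1]]) > 1) {
      tables[[1]] <- tgxcurate:::drop_columns(tables[[1]], 1L)
    }
    tv <- temp_vocabulary()
    # occasionally stage one observed unknown so AMBER paths are exercised
    feats <- unique(unlist(lapply(tables, names)))
    for (f in feats) {
      got <- status_of_feature(f, tables, fx$vocabulary, tv)$status
      want <- oracle_status(f, tables, fx$vocabulary, tv)
      expect_identical(got, want, info = sprintf("seed %d feature %s",
                                                 300 + i, f))
      n_checked <- n_checked + 1
    }
  }
  expect_gte(n_checked, 100)
})

test_that("integration stacks all samples, sorts features, and fills absences", {
  w <- two_curated_tables()
  v <- vocabulary(features = c(
    w$v$features,
    list(dose = feature_entry(
      "dose", instances = list(`10` = character(0), `20` = character(0))))))
  t2 <- metadata_table(tibble::tibble(d = c("10", "20")), "geo2",
                       headers = "dose")
  out <- integrate_tables(list(w$tables[[1]], t2), v)
  expect_identical(names(out$table),
                   c("dataset_id", "sample_id", "dose", "ethnicity"))
  expect_identical(nrow(out$table), 4L)
  expect_identical(out$table$dose, c("", "", "10", "20"))
  expect_identical(out$table$sample_id,
                   c("geo1_1", "geo1_2", "geo2_1", "geo2_2"))
  expect_identical(out$report$feature_rows$status, c("AMBER", "AMBER"))
})

test_that("disjoint-feature integration makes every feature AMBER by presence", {
  v <- ethnicity_vocabulary()
  v2 <- merge_temp(v, stage_term(temp_vocabulary(), v, term = "dose",
                                 as_kind = "feature"),
                   c("feature:dose" = "approve"))$vocabulary
  t1 <- metadata_table(tibble::tibble(x = "Black"), "a", headers = "ethnicity")
  t2 <- metadata_table(tibble::tibble(x = ""), "b", headers = "dose")
  out <- integrate_tables(list(t1, t2), v2)
  expect_true(all(out$report$feature_rows$status == "AMBER"))
})

test_that("a table integrated with its own copy is all-GREEN with doubled rows", {
  w <- two_curated_tables()
  t1 <- w$tables[[1]]
  t1b <- t1
  attr(t1b, "dataset_id") <- "copy"
  out <- integrate_tables(list(t1, t1b), w$v)
  expect_true(all(out$report$feature_rows$status == "GREEN"))
  expect_identical(nrow(out$table), 2L * nrow(t1))
})

test_that("integration conserves rows and cell multisets per feature", {
  for (seed in 1:5) {
    fx <- make_fixture(fixture_spec(seed = seed,
                                    corruption = solvable_profile()))
    ses <- curate_fixture(fx)
    tables <- lapply(ses$curation_states, curated_table)
    out <- integrate_tables(unname(tables), fx$vocabulary, ses$temp_vocab)
    expect_identical(nrow(out$table),
                     sum(vapply(tables, nrow, integer(1))))
    for (f in names(fx$vocabulary$features)) {
      got <- sort(out$table[[f]])
      want <- sort(unlist(lapply(tables, function(t)
        if (f %in% names(t)) as.character(t[[f]]) else character(0))))
      expect_identical(got, unname(want))
    }
  }
})

test_that("permuting input order permutes only the documented dataset ordering", {
  fx <- make_fixture(fixture_spec(seed = 5, n_datasets = 3,
                                  corruption = solvable_profile()))
  ses <- curate_fixture(fx)
  tables <- unname(lapply(ses$curation_states, curated_table))
  base <- integrate_tables(tables, fx$vocabulary, ses$temp_vocab)
  strip_time <- function(r) { l <- tgxcurate:::report_to_list(r); l$generated_at <- NULL; l }
  for (perm in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    out <- integrate_tables(tables[perm], fx$vocabulary, ses$temp_vocab)
    # per-feature statuses identical regardless of order
    expect_identical(
      stats::setNames(out$report$feature_rows$status,
                      out$report$feature_rows$feature),
      stats::setNames(base$report$feature_rows$status,
                      base$report$feature_rows$feature))
    # integrated rows identical after sorting by dataset
    reord <- dplyr::arrange(out$table, .data$dataset_id, .data$sample_id)
    baseord <- dplyr::arrange(base$table, .data$dataset_id, .data$sample_id)
    expect_identical(reord, baseord)
  }
})

test_that("adding a resolving vocabulary entry never lowers a status", {
  fx <- make_fixture(fixture_spec(
    seed = 9, corruption = corruption_profile(p_unknown_term = 0.1,
                                              p_missing = 0)))
  ses <- curate_fixture(fx)
  tables <- unname(lapply(ses$curation_states, curated_table))
  before <- integrate_tables(tables, fx$vocabulary)$report
  # promote every staged unknown into the reference vocabulary
  dec <- stats::setNames(rep("approve", nrow(ses$temp_vocab$entries)),
                         ses$temp_vocab$entries$entry_id)
  v2 <- merge_temp(fx$vocabulary, ses$temp_vocab, dec)$vocabulary
  after <- integrate_tables(tables, v2)$report
  ord <- c(RED = 1, AMBER = 2, GREEN = 3)
  b <- stats::setNames(before$feature_rows$status, before$feature_rows$feature)
  a <- stats::setNames(after$feature_rows$status, after$feature_rows$feature)
  expect_true(all(ord[a[names(b)]] >= ord[b]))
  expect_true(any(b == "RED"))
  expect_false(any(a == "RED"))
})

test_that("integration requires at least two distinct datasets", {
  w <- two_curated_tables()
  expect_error(integrate_tables(w$tables[1], w$v), "at least two")
  dup <- w$tables
  attr(dup[[2]], "dataset_id") <- "geo1"
  expect_error(integrate_tables(dup, w$v), "duplicate dataset identifiers")
})

test_that("issues append with history preserved and feed the next round", {
  w <- two_curated_tables()
  out <- integrate_tables(w$tables, w$v)
  r <- out$report
  expect_error(mark_issue(r, "ethnicity", note = ""), "non-empty note")
  expect_error(mark_issue(r, "nope", note = "x"), "does not appear")
  r <- mark_issue(r, "ethnicity", note = "instance coding unclear",
                  actor = "tester")
  r <- mark_issue(r, "ethnicity", instance = "Black", note = "recheck",
                  actor = "tester")
  expect_identical(nrow(r$issues), 2L)
  tasks <- issues_for_next_round(r)
  expect_identical(nrow(tasks), 4L)  # 2 issues x 2 datasets with the feature
  r <- resolve_issue(r, 1)
  expect_identical(nrow(issues_for_next_round(r)), 2L)
  r2 <- resolve_issue(r, 2)
  expect_identical(nrow(issues_for_next_round(r2)), 0L)
})

test_that("machine reports round-trip and human reports render one line per feature", {
  p <- withr::local_tempfile(fileext = ".json")
  h <- withr::local_tempfile(fileext = ".md")
  for (seed in 1:10) {
    fx <- make_fixture(fixture_spec(seed = seed, n_datasets = 2,
                                    rows_per_dataset = 5))
    ses <- curate_fixture(fx)
    tables <- unname(lapply(ses$curation_states, curated_table))
    r <- integrate_tables(tables, fx$vocabulary, ses$temp_vocab)$report
    if (seed %% 2 == 0) r <- mark_issue(r, r$feature_rows$feature[[1]],
                                        note = "check me", actor = "t")
    export_report(r, p, "machine")
    expect_identical(tgxcurate:::report_to_list(import_report(p)),
                     tgxcurate:::report_to_list(r))
    export_report(r, h, "human")
    lines <- readLines(h)
    body <- grep("^\\| [^-]", lines, value = TRUE)
    expect_identical(length(body) - 1L, nrow(r$feature_rows))  # minus header
    expect_true(all(r$feature_rows$status %in%
                      c("GREEN", "AMBER", "RED")))
  }
})
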