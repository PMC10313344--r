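#' Synthetic fixture specifications
#'
#' The fixture generator produces ground-truthed material for every pipeline
#' stage with no external data: a collision-free random vocabulary, fully
#' canonical ground-truth tables drawn from it, and messy copies corrupted by
#' a configurable profile together with the exact cell-level messy-to-truth
#' mapping for scoring. Identical specifications yield identical fixtures;
#' the three generation steps consume derived seeds (`seed`, `seed + 1`,
#' `seed + 2`) so any step can be regenerated without the others.
#'
#' Generated terms are pronounceable alternating consonant-vowel strings,
#' which keeps single-character typo corruption meaningful for fuzzy-matching
#' tests.
#'
#' @param seed Integer master seed.
#' @param n_features Number of canonical features (>= 1).
#' @param instances_per_feature Length-2 integer range of canonical instances
#'   per feature.
#' @param synonyms_per_term Length-2 integer range of synonyms per canonical
#'   term (0 allowed: some terms have no alternative spellings).
#' @param n_datasets Number of tables to generate (>= 1).
#' @param rows_per_dataset Samples per table (>= 1).
#' @param corruption A [corruption_profile()].
#' @param feature_names Optional character vector of canonical feature names
#'   to use instead of generated ones (recycled/truncated to `n_features`).
#' @return A `tgx_fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_features = 5L,
                         instances_per_feature = c(2L, 4L),
                         synonyms_per_term = c(0L, 2L),
                         n_datasets = 2L, rows_per_dataset = 20L,
                         corruption = corruption_profile(),
                         feature_names = NULL) {
  stopifnot(n_features >= 1L, n_datasets >= 1L, rows_per_dataset >= 1L,
            length(instances_per_feature) == 2L,
            min(instances_per_feature) >= 1L,
            length(synonyms_per_term) == 2L, min(synonyms_per_term) >= 0L)
  structure(
    list(seed = as.integer(seed), n_features = as.integer(n_features),
         instances_per_feature = as.integer(instances_per_feature),
         synonyms_per_term = as.integer(synonyms_per_term),
         n_datasets = as.integer(n_datasets),
         rows_per_dataset = as.integer(rows_per_dataset),
         corruption = corruption, feature_names = feature_names),
    class = "tgx_fixture_spec")
}

#' @rdname fixture_spec
#' @param p_synonym_swap Probability a header/cell is replaced by a known
#'   synonym of its canonical term (recoverable by exact-policy curation).
#' @param p_case_mangle Probability of random case flips (recoverable: lookup
#'   is case-insensitive).
#' @param p_typo Probability of a single-character edit (only recoverable by
#'   human-confirmed fuzzy matching).
#' @param p_missing Probability a cell is blanked with a missing token
#'   (information-destroying; never recoverable).
#' @param p_duplicate_column Probability a column is duplicated (verbatim
#'   copy of the corrupted column, possibly under a different synonym
#'   header).
#' @param p_unknown_term Probability a cell is replaced by a term absent from
#'   the vocabulary (surfaces in [unmatched_terms()] and as RED statuses).
#' @export
corruption_profile <- function(p_synonym_swap = 0.4, p_case_mangle = 0.2,
                               p_typo = 0, p_missing = 0.05,
                               p_duplicate_column = 0.1,
                               p_unknown_term = 0) {
  p <- c(p_synonym_swap = p_synonym_swap, p_case_mangle = p_case_mangle,
         p_typo = p_typo, p_missing = p_missing,
         p_duplicate_column = p_duplicate_column,
         p_unknown_term = p_unknown_term)
  stopifnot(all(p >= 0), all(p <= 1))
  as.list(p)
}

# pronounceable consonant-vowel strings, e.g. "tamo", "rilupa"
random_term <- function(n_syllables = sample(2:3, 1)) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t", "v", "z")
  vow <- c("a", "e", "i", "o", "u")
  paste0(paste0(sample(cons, n_syllables, replace = TRUE),
                sample(vow, n_syllables, replace = TRUE)), collapse = "")
}

# draw a term whose normalized form is not yet used; updates the used set
fresh_term <- function(used) {
  repeat {
    t <- random_term()
    if (!normalize_term(t) %in% used) return(t)
  }
}

cap <- function(x) paste0(toupper(substr(x, 1, 1)), substr(x, 2, nchar(x)))

#' Generate a random valid vocabulary
#'
#' All generated terms (features, feature synonyms, instances, instance
#' synonyms) are globally collision-free in normalized space, so the result
#' always validates cleanly and every synonym resolves unambiguously.
#' Deterministic in `spec$seed`.
#'
#' @param spec A [fixture_spec()].
#' @return A `tgx_vocabulary`.
#' @export
make_vocabulary <- function(spec) {
  set.seed(spec$seed)
  used <- character(0)
  take <- function() {
    t <- fresh_term(used)
    used <<- c(used, normalize_term(t))
    t
  }
  nsyn <- function() sample(seq(spec$synonyms_per_term[1],
                                spec$synonyms_per_term[2]), 1)
  ninst <- function() sample(seq(spec$instances_per_feature[1],
                                 spec$instances_per_feature[2]), 1)

  feats <- list()
  for (i in seq_len(spec$n_features)) {
    fname <- if (!is.null(spec$feature_names) &&
                 i <= length(spec$feature_names) &&
                 !normalize_term(spec$feature_names[[i]]) %in% used) {
      used <- c(used, normalize_term(spec$feature_names[[i]]))
      spec$feature_names[[i]]
    } else take()
    fsyn <- replicate(nsyn(), take())
    inst <- list()
    for (j in seq_len(ninst())) {
      iname <- cap(take())
      inst[[iname]] <- as.character(replicate(nsyn(), take()))
    }
    feats[[fname]] <- feature_entry(fname, synonyms = as.character(fsyn),
                                    instances = inst)
  }
  vocabulary(name = sprintf("fixture-vocabulary-%d", spec$seed),
             version = "1", features = feats,
             provenance_note = "synthetic fixture vocabulary")
}

#' Generate fully canonical ground-truth tables
#'
#' Headers are the canonical features in vocabulary order; every cell is a
#' canonical instance of its feature, so curating a ground-truth table
#' proposes only no-ops. Deterministic in `spec$seed + 1`.
#'
#' @param spec A [fixture_spec()].
#' @param v The vocabulary from [make_vocabulary()].
#' @return List of `tgx_table` objects, dataset ids `dataset01`,
#'   `dataset02`, ...
#' @export
make_ground_truth_tables <- function(spec, v) {
  set.seed(spec$seed + 1L)
  feats <- names(v$features)
  lapply(seq_len(spec$n_datasets), function(d) {
    cols <- lapply(feats, function(f) {
      inst <- names(v$features[[f]]$instances)
      sample(inst, spec$rows_per_dataset, replace = TRUE)
    })
    names(cols) <- feats
    metadata_table(tibble::as_tibble(cols, .name_repair = "minimal"),
                   dataset_id = sprintf("dataset%02d", d))
  })
}

mangle_case <- function(x) {
  chars <- strsplit(x, "")[[1]]
  flip <- stats::runif(length(chars)) < 0.5
  chars[flip] <- toupper(chars[flip])
  paste0(chars, collapse = "")
}

typo <- function(x) {
  if (nchar(x) < 2L) return(paste0(x, "x"))
  i <- sample(nchar(x), 1)
  op <- sample(c("sub", "del", "ins"), 1)
  if (op == "sub") {
    # never substitute a letter by itself (in either case), so a typo always
    # changes the normalized form
    pool <- setdiff(letters, tolower(substr(x, i, i)))
    substr(x, i, i) <- sample(pool, 1)
    x
  } else if (op == "del") {
    paste0(substr(x, 1, i - 1), substr(x, i + 1, nchar(x)))
  } else {
    paste0(substr(x, 1, i), sample(letters, 1),
           substr(x, i + 1, nchar(x)))
  }
}

#' Corrupt ground-truth tables into messy fixtures
#'
#' Applies, per the corruption profile: header and cell synonym swaps, case
#' mangling, single-character typos, missing tokens, unknown terms, and
#' duplicated columns (verbatim copies of the corrupted column, possibly
#' under a different synonym header, so a later cell-wise merge is safe by
#' construction). Returns the messy tables and the exact messy-to-truth
#' mapping used for recovery scoring. Deterministic in `spec$seed + 2`.
#'
#' @param tables Ground-truth tables from [make_ground_truth_tables()].
#' @param v The vocabulary.
#' @param spec The [fixture_spec()].
#' @return List with `tables` (messy `tgx_table`s) and `mapping` (tibble:
#'   `dataset_id`, `kind` header/cell/dup_column, `row`, `col`, `truth`,
#'   `messy`, `corruption`).
#' @export
corrupt_tables <- function(tables, v, spec) {
  set.seed(spec$seed + 2L)
  p <- spec$corruption
  missing_pool <- c("", "NA", "N/A", "-", "null")
  vocab_terms <- normalize_term(unlist(c(
    names(v$features),
    lapply(v$features, function(f) c(f$synonyms, names(f$instances),
                                     unlist(f$instances))))))
  map_rows <- list()
  note <- function(...) map_rows[[length(map_rows) + 1L]] <<- tibble::tibble(...)

  messy <- lapply(tables, function(t) {
    ds <- dataset_id(t)
    feats <- names(t)
    cols <- list()
    headers <- character(0)

    for (ci in seq_along(feats)) {
      f <- feats[[ci]]
      fe <- v$features[[f]]
      # header corruption
      h <- f
      hkind <- "none"
      if (stats::runif(1) < p$p_synonym_swap && length(fe$synonyms) > 0L) {
        h <- sample(fe$synonyms, 1); hkind <- "synonym"
      }
      if (stats::runif(1) < p$p_case_mangle) {
        h <- mangle_case(h); hkind <- paste0(hkind, "+case")
      }
      if (stats::runif(1) < p$p_typo) {
        h <- typo(h); hkind <- paste0(hkind, "+typo")
      }
      note(dataset_id = ds, kind = "header", row = NA_integer_, col = ci,
           truth = f, messy = h, corruption = hkind)

      # cell corruption; every cell lands in the mapping with its kind
      corrupted <- lapply(t[[ci]], function(val) {
        ckind <- "none"
        out <- val
        r <- stats::runif(1)
        if (r < p$p_missing) {
          out <- sample(missing_pool, 1); ckind <- "missing"
        } else if (r < p$p_missing + p$p_unknown_term) {
          repeat {
            u <- random_term()
            if (!normalize_term(u) %in% vocab_terms) break
          }
          out <- u; ckind <- "unknown"
        } else {
          syn <- fe$instances[[val]]
          if (stats::runif(1) < p$p_synonym_swap && length(syn) > 0L) {
            out <- sample(syn, 1); ckind <- "synonym"
          }
          if (stats::runif(1) < p$p_case_mangle) {
            out <- mangle_case(out)
            ckind <- if (ckind == "none") "case" else paste0(ckind, "+case")
          }
          if (stats::runif(1) < p$p_typo) {
            out <- typo(out)
            ckind <- if (ckind == "none") "typo" else paste0(ckind, "+typo")
          }
        }
        list(value = out, kind = ckind)
      })
      cells <- vapply(corrupted, `[[`, character(1), "value")
      kinds <- vapply(corrupted, `[[`, character(1), "kind")
      note(dataset_id = rep(ds, length(cells)), kind = rep("cell", length(cells)),
           row = seq_along(cells), col = rep(ci, length(cells)),
           truth = as.character(t[[ci]]), messy = cells, corruption = kinds)
      cols[[length(cols) + 1L]] <- cells
      headers <- c(headers, h)

      # duplicated column: verbatim copy, maybe under another synonym header
      if (stats::runif(1) < p$p_duplicate_column) {
        h2 <- if (length(fe$synonyms) > 0L && stats::runif(1) < 0.5)
          sample(c(f, fe$synonyms), 1) else h
        cols[[length(cols) + 1L]] <- cells
        headers <- c(headers, h2)
        note(dataset_id = ds, kind = "dup_column", row = NA_integer_,
             col = ci, truth = f, messy = h2, corruption = "duplicate")
      }
    }
    names(cols) <- headers
    metadata_table(tibble::as_tibble(cols, .name_repair = "minimal"),
                   dataset_id = ds, headers = headers)
  })

  list(tables = messy, mapping = dplyr::bind_rows(map_rows))
}

#' Generate a complete fixture
#'
#' Convenience wrapper running [make_vocabulary()],
#' [make_ground_truth_tables()] and [corrupt_tables()] in order.
#'
#' @param spec A [fixture_spec()].
#' @return List with `vocabulary`, `truth`, `messy`, `mapping`.
#' @export
make_fixture <- function(spec) {
  v <- make_vocabulary(spec)
  truth <- make_ground_truth_tables(spec, v)
  cr <- corrupt_tables(truth, v, spec)
  list(vocabulary = v, truth = truth, messy = cr$tables, mapping = cr$mapping)
}

#' Read and write fixture specifications
#'
#' @param spec A `tgx_fixture_spec`.
#' @param path JSON file path.
#' @export
save_fixture_spec <- function(spec, path) {
  write_json_atomic(unclass(spec), path)
  invisible(path)
}

#' @rdname save_fixture_spec
#' @export
load_fixture_spec <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  fixture_spec(
    seed = doc$seed, n_features = doc$n_features,
    instances_per_feature = doc$instances_per_feature,
    synonyms_per_term = doc$synonyms_per_term,
    n_datasets = doc$n_datasets, rows_per_dataset = doc$rows_per_dataset,
    corruption = do.call(corruption_profile, as.list(doc$corruption)),
    feature_names = doc$feature_names)
}
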