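# Shared fixtures and independent oracles for the suite.

# The demographic worked example: 'ethnicity' (synonym 'race') with
# instances Black [B, African-American], White [Caucasian, C], Inuit [].
ethnicity_vocabulary <- function() {
  vocabulary(
    name = "ethnicity-demo", version = "1",
    features = list(ethnicity = feature_entry(
      "ethnicity", synonyms = "race",
      instances = list(Black = c("B", "African-American"),
                       White = c("Caucasian", "C"),
                       Inuit = character(0)))))
}

ethnicity_table <- function(values = c("Caucasian", "B", "Inuit",
                                       "African-American", "C"),
                            header = "race", dataset_id = "geo1") {
  df <- tibble::tibble(x = values)
  metadata_table(df, dataset_id = dataset_id, headers = header)
}

# independent Levenshtein oracle: hand-written dynamic programme, no adist
oracle_levenshtein <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L) return(nb)
  if (nb == 0L) return(na)
  ac <- strsplit(a, "")[[1]]; bc <- strsplit(b, "")[[1]]
  prev <- 0:nb
  for (i in seq_len(na)) {
    cur <- c(i, integer(nb))
    for (j in seq_len(nb)) {
      cost <- if (ac[[i]] == bc[[j]]) 0L else 1L
      cur[[j + 1L]] <- min(prev[[j + 1L]] + 1L, cur[[j]] + 1L,
                           prev[[j]] + cost)
    }
    prev <- cur
  }
  prev[[nb + 1L]]
}

# oracle for the token-set similarity used in fuzzy ranking
oracle_similarity <- function(a, b) {
  canon <- function(x) {
    toks <- strsplit(normalize_term(x), " ", fixed = TRUE)[[1]]
    paste(sort(unique(toks[nzchar(toks)])), collapse = " ")
  }
  a <- canon(a); b <- canon(b)
  mx <- max(nchar(a), nchar(b))
  if (mx == 0L) return(1)
  1 - oracle_levenshtein(a, b) / mx
}

# brute-force fuzzy ranking over every term of a vocabulary's feature index
oracle_feature_ranking <- function(v, query, threshold) {
  idx <- do.call(rbind, lapply(v$features, function(f)
    data.frame(term = c(f$canonical_name, f$synonyms),
               canonical = f$canonical_name)))
  sims <- vapply(idx$term, function(tm) oracle_similarity(query, tm),
                 numeric(1))
  agg <- tapply(sims, idx$canonical, max)
  agg <- agg[agg >= threshold]
  agg[order(-agg, names(agg))]
}

# brute-force pairwise synonym-collision scan used against validate_vocabulary
oracle_collisions <- function(v) {
  viol <- 0L
  idx <- do.call(rbind, lapply(v$features, function(f)
    data.frame(term = normalize_term(c(f$canonical_name, f$synonyms)),
               canonical = f$canonical_name)))
  for (tm in unique(idx$term)) {
    if (length(unique(idx$canonical[idx$term == tm])) > 1L) viol <- viol + 1L
  }
  for (f in v$features) {
    iidx <- do.call(rbind, lapply(names(f$instances), function(ci)
      data.frame(term = normalize_term(c(ci, f$instances[[ci]])),
                 canonical = ci)))
    if (is.null(iidx)) next
    for (tm in unique(iidx$term)) {
      if (length(unique(iidx$canonical[iidx$term == tm])) > 1L)
        viol <- viol + 1L
    }
  }
  viol
}

# random vocabulary that may contain deliberate collisions
random_messy_vocabulary <- function(n_features = 3, p_collide = 0.3) {
  terms <- replicate(n_features * 6,
                     paste0(sample(letters, sample(3:6, 1), TRUE),
                            collapse = ""))
  terms <- unique(terms)
  feats <- list()
  for (i in seq_len(n_features)) {
    nm <- terms[[i]]
    syn <- if (runif(1) < p_collide && i > 1) {
      # reuse another feature's name to force a collision
      terms[[sample(i - 1, 1)]]
    } else if (length(terms) >= n_features + i) terms[[n_features + i]]
      else character(0)
    feats[[nm]] <- feature_entry(nm, synonyms = syn)
  }
  structure(list(name = "messy", version = "1", provenance_note = "",
                 features = feats),
            class = "tgx_vocabulary")
}

solvable_profile <- function() {
  corruption_profile(p_synonym_swap = 0.5, p_case_mangle = 0.3, p_typo = 0,
                     p_missing = 0, p_duplicate_column = 0.2,
                     p_unknown_term = 0)
}

expect_tables_equal <- function(a, b) {
  expect_identical(names(a), names(b))
  expect_identical(unname(lapply(a, as.character)),
                   unname(lapply(b, as.character)))
}

# curate every messy table of a fixture with the exact-match batch policy
curate_fixture <- function(fx, glp_mode = FALSE, fuzzy_threshold = 0.85) {
  ses <- new_session(fx$vocabulary, session_id = "fixture-session",
                     glp_mode = glp_mode, actor = "tester")
  for (t in fx$messy) {
    st <- curate_auto(t, fx$vocabulary, glp_mode = glp_mode, actor = "tester",
                      fuzzy_threshold = fuzzy_threshold,
                      temp_vocab = ses$temp_vocab, audit = ses$audit)
    ses$curation_states[[dataset_id(t)]] <- st
    ses$temp_vocab <- st$temp_vocab
    ses$audit <- st$audit
  }
  ses
}

# brute-force evaluation of the three colour rules, independent of
# status_of_feature's implementation
oracle_status <- function(feature, tables, v, t) {
  # independent feature resolution: scan every feature's canonical + synonyms
  ref_key <- NA_character_
  for (f in v$features) {
    if (normalize_term(feature) %in%
          normalize_term(c(f$canonical_name, f$synonyms))) {
      ref_key <- f$canonical_name
      break
    }
  }
  resolves_ref_feat <- !is.na(ref_key)
  temp_feats <- t$entries[t$entries$as_kind == "feature" &
                            t$entries$status %in% c("pending", "approved"), ]
  resolves_temp_feat <- normalize_term(feature) %in%
    normalize_term(temp_feats$term)
  present <- vapply(tables, function(tab)
    normalize_term(feature) %in% normalize_term(names(tab)), logical(1))
  worst <- "GREEN"
  demote <- function(w, lv) {
    ord <- c(RED = 1, AMBER = 2, GREEN = 3)
    if (ord[[lv]] < ord[[w]]) lv else w
  }
  if (!resolves_ref_feat) {
    worst <- demote(worst, if (resolves_temp_feat) "AMBER" else "RED")
  }
  if (any(!present)) worst <- demote(worst, "AMBER")
  for (j in which(present)) {
    tab <- tables[[j]]
    ci <- which(normalize_term(names(tab)) == normalize_term(feature))
    vals <- unique(unlist(lapply(ci, function(k) tab[[k]])))
    vals <- vals[!is_missing_cell(vals)]
    for (val in vals) {
      in_ref <- FALSE
      if (resolves_ref_feat) {
        fe <- v$features[[ref_key]]
        for (inst in names(fe$instances)) {
          if (normalize_term(val) %in%
                normalize_term(c(inst, fe$instances[[inst]]))) {
            in_ref <- TRUE
            break
          }
        }
      }
      tmp <- t$entries[t$entries$as_kind == "instance" &
                         t$entries$status %in% c("pending", "approved"), ]
      in_tmp <- any(normalize_term(tmp$term) == normalize_term(val) &
                      normalize_term(tmp$feature_key) ==
                        normalize_term(feature))
      if (!in_ref) worst <- demote(worst, if (in_tmp) "AMBER" else "RED")
    }
  }
  worst
}

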