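---
title: "Semi-supervised metadata harmonization: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semi-supervised metadata harmonization: model, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tgxcurate)
```

## The problem

Public omics repositories hold large volumes of toxicogenomics data whose
sample annotations — dose, exposure time, tissue, compound, demographics —
were written as free text by many hands. The same concept appears as `race`,
`Race`, `ethnicity` or `patient_background`; the same value as `Caucasian`,
`C` or `White`. Fully automatic harmonization is unreliable because these
mappings are judgement calls, and fully manual curation is slow and
undocumented. This package implements the middle road: the machine proposes
every harmonization it can justify from a controlled vocabulary, and a human
(or a scripted decision file standing in for one) accepts, rejects or edits
each proposal before anything changes. Every decision lands in an audit log
detailed enough to replay the entire curation deterministically — the
documentation discipline that Good Laboratory Practice (GLP) expects.

## The vocabulary model

The reference vocabulary is two linked layers of canonical-term-to-synonym
maps:

* **features** — column concepts (`ethnicity`, `dose`, `tissue`), each with a
  set of synonyms (`race` for `ethnicity`);
* **instances** — per feature, the values that feature may take (`Black`,
  `White`, `Inuit`), each with its own synonyms (`B`, `African-American` for
  `Black`).

A canonical term is implicitly a synonym of itself, and synonym sets may be
empty (`Inuit` has none). Validity means resolution is a *function*: after
normalization no term maps to more than one canonical feature, and within a
feature no term maps to more than one canonical instance.
`validate_vocabulary()` enforces exactly this, and every load/save/merge
revalidates. An empty vocabulary is a legal starting point; any existing
ontology restructured into this shape can be used.

Term comparison happens in a normalized space (`normalize_term()`):
lower-casing, trimming, whitespace collapsing, and replacement of the
punctuation set `_ . , ; : / ( ) -` by spaces. Canonical terms keep their
display casing. Normalization is deliberately idempotent so it can be
applied defensively anywhere.

### Matching, in three gated steps

`lookup_feature()` / `lookup_instance()` resolve a query term by

1. exact text equality (score 1.0),
2. equality after normalization (score 1.0),
3. optionally, fuzzy ranking by a token-set normalized-Levenshtein
   similarity, kept when the best score reaches `fuzzy_threshold`
   (default **0.85**, range 0–1; values above 1 disable fuzzy matching).

The similarity sorts and deduplicates the word tokens of both normalized
terms before computing `1 - distance / max(length)`, so word order and
repetition never matter. Fuzzy hits are *never* auto-applied by any driver
in this package — they only ever become proposals for a human, because a
near-miss spelling is precisely the case where silent automation goes wrong.
Ties at the top fuzzy score are reported as ambiguous with no winner: the
tool does not guess for the user. The 0.85 default tolerates roughly one
edit in a seven-character term, which in practice captures typos without
pulling in unrelated vocabulary; it is a starting point to be tuned per
vocabulary, not a claim about optimality.

## The three-stage curation pipeline

Curation of one table proceeds through monotone stages —
`rename → dedup → values → done` — mirroring how inconsistency actually
nests in these tables: you cannot align values before columns are named
consistently, and you cannot merge duplicate columns before renaming reveals
them.

1. **Column renaming.** One proposal per header via feature lookup.
   Already-canonical headers produce auto-acceptable no-ops; unresolvable
   headers get no suggestion and become candidates for the temporary
   vocabulary.
2. **Duplicate columns.** Columns are duplicates when their *normalized
   headers* are equal; cell content only decides whether a merge is safe.
   The per-row agreement summary marks rows whose non-missing cells
   disagree. Resolution is per group: coalesce (first non-missing value
   wins; conflicting rows block the merge and must be edited first), keep
   one named column, or keep everything.
3. **Value harmonization.** For each column whose header is a canonical
   feature, one proposal per *unique* non-missing value (never per cell);
   accepting rewrites every equal cell in that column. Columns with no
   vocabulary feature are left untouched — they surface later in the
   integration report rather than being silently "fixed".

Missing cells are those whose normalized text equals one of
`"", "NA", "N/A", "na", "null", "-"` (configurable). The list drives both
the duplicate-merge coalescing and the exclusion of missing values from
harmonization proposals; the defaults cover the tokens that dominate
repository exports.

`apply_decision()` is the single gate through which data changes, and it
appends to the audit log *before* mutating, so a failed GLP check aborts the
action with no state change. Proposal identifiers are deterministic in
(stage, column position, normalized term), which keeps decision files valid
across re-runs; raw-distinct values sharing a normalized form get stable
order-of-appearance suffixes.

Terms the vocabulary cannot resolve are staged into the **temporary
vocabulary** with status `pending` — the same amber/green/red colour logic
used elsewhere (`pending`/`approved`/`rejected`). Staged entries never
shadow the reference vocabulary, and `merge_temp()` promotes approved
entries atomically: if any approval would create a collision, nothing
merges.

## Integration and the traffic-light report

`integrate_tables()` aligns two or more curated tables on the union of
their features (sorted by name), stacks all samples with dataset provenance
and a synthesized `sample_id` where none exists, and classifies every
feature:

* **GREEN** — reference-canonical feature, present in all datasets, all
  observed instances resolve in the reference vocabulary;
* **AMBER** — the only defects are temporary-vocabulary-only resolution or
  absence from some dataset;
* **RED** — the feature or an observed instance resolves in neither
  vocabulary, or the same normalized header maps to different canonical
  features across datasets.

The overall status is the minimum over all checks (RED < AMBER < GREEN), a
deliberately conservative aggregation: a single unknown instance is enough
to flag a feature, because in a risk-assessment context a false "all clear"
costs more than a false alarm. Temporary-vocabulary hits are capped at
AMBER so that a dataset can only be declared fully consistent after explicit
promotion into the reference vocabulary. The granularity question — whether
the colour applies per feature or per instance — is resolved by computing
both: instance-level defects are enumerated in `reasons`, and the feature
row aggregates them.

RED is a finding, not a failure: integration runs exit 0 and leave the
discrepancies in the report, where `mark_issue()` can flag them (history
preserved — flags are never overwritten) and `issues_for_next_round()`
turns unresolved flags into per-dataset curation tasks.

## Audit, GLP mode and replay

Every action — including rejections and kept-intact duplicate groups — is
recorded with a gapless sequence number, UTC timestamp, actor, dataset,
target, before/after values and justification. GLP mode is fixed at session
creation (a partially-GLP report is not GLP) and requires at least one
non-whitespace character of justification on every action; the package
checks presence, not prose quality, because no tool can score the substance
of a justification. In non-GLP mode justifications are optional but
recorded.

`replay()` re-executes a log against the original tables and starting
vocabulary. Design choices that make replay exact:

* timestamps are recorded for the report but excluded from replay semantics
  and structural comparison — reproducibility must not depend on wall-clock;
* merge/delete records carry JSON-encoded column *positions*, because
  duplicate columns share a header and a name cannot identify which column
  was dropped;
* a record that no longer applies (its target is absent or its before-text
  does not match) fails with that record's sequence number, signalling a
  log/input mismatch rather than silently diverging.

Accepted no-op proposals (suggestion identical to the current text) are
recorded with identical before/after fields; they document the decision
without constituting a data change, so the audit-to-diff reconciliation
remains one change per differing record.

Sessions serialize to one versioned JSON document embedding vocabulary,
temporary vocabulary, per-dataset curation states, integration result and
log; `load_session()` restores a structurally identical value and refuses
other format versions by name.

## The synthetic-fixture generator

`make_fixture()` produces the material every test runs on: a random valid
vocabulary of pronounceable consonant-vowel terms (globally collision-free
in normalized space, so typo corruption stays meaningful for fuzzy
matching), fully canonical ground-truth tables, and messy copies corrupted
per profile with the exact cell-level messy-to-truth mapping retained for
scoring. The defaults — 5 features, 2–4 instances per feature, 0–2 synonyms
per term, 2 datasets of 20 samples — are sized like a typical repository
series annotation table; the corruption defaults (40% synonym swaps, 20%
case mangling, 5% missing, 10% duplicated columns, no typos or unknown
terms) emulate the dominant forms of annotation inconsistency while staying
exactly solvable by the accept-exact-matches policy.

Determinism: the three generation steps consume seeds derived from the
master seed (`seed`, `seed + 1`, `seed + 2` for vocabulary, tables,
corruption), so the whole fixture is a pure function of its specification
and any step can be regenerated without re-running the others. Duplicated
columns are verbatim copies of the *corrupted* column (possibly under a
different synonym header): since the stages are monotone, a merge-safe
duplicate must agree cell-wise in raw text at dedup time, and independently
re-corrupted copies would conflict by construction.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: semantic near-synonyms absent from the vocabulary
("PBS control" vs "vehicle"), multi-valued cells, structured values with
units, non-Latin scripts, and columns whose duplication carries conflicting
measurements. Corruption kinds also bound recovery honestly: cells replaced
by missing tokens destroy information no curation policy can restore, which
is why the exact-recovery property is stated for synonym/case corruption
only, and why typo and unknown-term corruption are measured against the
stored mapping instead of against perfection.

## Batch drivers and numerical edge cases

`curate_auto()` (and the `tgxcurate` command-line script over it) resolves
proposals by precedence: explicit decision-file entry, then the
auto-accept-exact policy (exact/normalized hits only), then rejection with a
default justification. Unresolved duplicate groups merge automatically only
when every row agrees; conflicting groups are kept intact and flagged. In
GLP mode a decision file is validated up front — one missing justification
aborts the run before any action. Proposals left undecided in a batch run
are rejected (with the default justification) so the run always reaches a
reportable, replayable end state; an interactive curator would instead keep
the session open.

Degenerate inputs behave as follows: empty vocabularies validate and
propose nothing; tables with one column and duplicate headers curate
normally; zero-row tables produce header proposals only; an empty audit log
replays to the originals; self-integration of a fully curated table is
all-GREEN by construction.

## Problem sizes used in the shipped checks

The test-suite and acceptance properties run at deliberately small scales —
hundreds of randomized sessions of 2–3 features × 4–8 samples for replay,
GLP and round-trip properties, 100 seeds of the default 2 × 20-sample
fixtures for exact recovery, and oracle comparisons on vocabularies of at
most ~50 terms and 3 datasets. These sizes exercise every code path
(duplicates, unknowns, missing values, ambiguity) while keeping a full run
in minutes on one CPU; none of the algorithms has state that grows with
table size beyond the table itself, so the properties are scale-free by
construction.

## Known limitations

* Matching is lexical. No stemming, no multilingual normalization, no
  embedding-based semantics; a synonym must be in the vocabulary to resolve.
* Harmonization operates on unique values per column; row-specific spot
  edits are out of scope, as are unit conversion and numeric-range checks.
* One curator per session; the audit log is honest but not tamper-evident
  (no cryptographic signing).
* OBO/OWL ontologies are not parsed directly; restructure them into the
  native JSON vocabulary format first.
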