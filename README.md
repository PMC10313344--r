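# tgxcurate

Semi-supervised harmonization and integration of toxicogenomics sample
metadata, with a GLP-style replayable audit trail.

## The problem

Sample annotation tables that accompany public toxicogenomics datasets are
free text written by many different submitters: the same column concept
appears as `race`, `Race` or `ethnicity`; the same value as `Caucasian`,
`C` or `White`; columns are duplicated; missing values are spelled five
ways. Integrating such datasets for chemical risk assessment requires
harmonizing all of it — reliably, and with a record of who changed what and
why, so the curated result meets Good Laboratory Practice (GLP)
documentation standards and the FAIR principles.

`tgxcurate` is for data curators and computational toxicologists who need
that harmonization to be *semi-supervised*: the package proposes every
change it can justify from a controlled vocabulary, a human (or a scripted
decision file) rules on each proposal, and nothing is ever changed
silently.

## The model in brief

A **vocabulary** is two linked layers of canonical-term → synonym maps:
features (column concepts, e.g. `ethnicity` with synonym `race`) and, per
feature, instances (values, e.g. `Black` with synonyms `B`,
`African-American`). Term resolution is gated: exact match, then match
after normalization (case/whitespace/punctuation), then — proposals only,
never auto-applied — fuzzy ranking by token-set normalized-Levenshtein
similarity with threshold 0.85.

**Curation** of one table runs in three monotone stages:
(i) column renaming, (ii) duplicate-column resolution (same normalized
header; first-non-missing-wins merge when rows agree), (iii) value
harmonization per unique value. Unresolvable terms are staged in a
**temporary vocabulary** (pending/approved/rejected) for later promotion.

**Integration** of several curated tables classifies every feature with a
traffic light — GREEN (canonical everywhere, all instances known), AMBER
(temporary-vocabulary terms or absence from a dataset), RED (unknown terms
or conflicting header mappings) — aggregated conservatively as the minimum
over all checks. Discrepancies can be flagged as Issues for the next
curation round.

Every action is appended to an **audit log** (gapless sequence numbers;
mandatory justification in GLP mode, enforced before any mutation), and
`replay()` re-executes a log against the original inputs to reproduce the
curated outputs exactly, independent of timestamps.

## Worked example

The package ships a small messy table and a matching vocabulary:

```r
library(tgxcurate)

v <- load_vocabulary(system.file("extdata", "ethnicity_vocabulary.json",
                                 package = "tgxcurate"))
t <- load_table(system.file("extdata", "geo_demo.csv",
                            package = "tgxcurate"), dataset_id = "geo_demo")
t
#> <tgx_table> dataset 'geo_demo': 5 sample(s) x 5 column(s)
#>   sample_id race             Race               age   dose
#> 1 GSM001    Caucasian        "Caucasian"        45    10 mg/kg
#> 2 GSM002    B                ""                 38    10 mg/kg
#> 3 GSM003    African-American "African-American" 51    0
#> 4 GSM004    Inuit            "Inuit"            NA    0
#> 5 GSM005    C                "C"                62    10 mg/kg
```

Curate it end to end with the batch policy (accept exact vocabulary
matches, reject and stage everything else):

```r
st <- curate_auto(t, v)
curated_table(st)
#> <tgx_table> dataset 'geo_demo': 5 sample(s) x 4 column(s)
#>   sample_id ethnicity age   dose
#> 1 GSM001    White     45    10 mg/kg
#> 2 GSM002    Black     38    10 mg/kg
#> 3 GSM003    Black     51    0
#> 4 GSM004    Inuit     NA    0
#> 5 GSM005    White     62    10 mg/kg
```

Both `race` columns were renamed to the canonical `ethnicity` and merged
(the second column's missing cell filled from the first); every value was
rewritten to its canonical instance. The audit log shows each step with its
before/after:

```r
tidy(st$audit)[, c("seq", "action_kind", "target", "before", "after")]
#>  1 reject      rename:001:sample id      sample_id        <NA>
#>  2 rename      column:2                  race             ethnicity
#>  3 rename      column:3                  Race             ethnicity
#>  ...
#>  6 merge       duplicate-group:ethnicity [2,3]            [2]
#>  7 replace     column:2:value            Caucasian        White
#>  8 replace     column:2:value            B                Black
#>  9 replace     column:2:value            African-American Black
#> ...
```

`age` and `dose` have no vocabulary feature, so they were left untouched,
staged in the temporary vocabulary, and surface in the integration report —
here a self-integration against a re-run of the same dataset:

```r
copy <- curated_table(st); attr(copy, "dataset_id") <- "geo_demo_rerun"
out <- integrate_tables(list(curated_table(st), copy), v, st$temp_vocab)
tidy(out$report)
#>   feature   status n_datasets_present n_reasons
#> 1 age       RED                     2         9
#> 2 dose      RED                     2         5
#> 3 ethnicity GREEN                   2         0
```

`ethnicity` is GREEN (fully canonical everywhere); `age` and `dose` are RED
findings — their values resolve in no vocabulary — to be fixed by extending
the vocabulary (`merge_temp()`) in the next round. `autoplot(out$report)`
draws the same table as a traffic-light tile plot, and `run_replay()`
verifies any saved session reproduces its outputs exactly.

A command-line interface wraps the same drivers:

```sh
tgxcurate curate --input geo_demo.csv --vocabulary vocabulary.json \
  --out results --glp --actor "A. Curator"
tgxcurate integrate --session results/session.json --out integration
tgxcurate replay --session results/session.json
```

(the script installs under `system.file("scripts", "tgxcurate",
package = "tgxcurate")`; exit codes: 0 success, 2 input error,
3 vocabulary error, 4 GLP violation, 5 replay divergence).

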