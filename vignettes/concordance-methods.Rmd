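---
title: "Measuring agreement between drug-drug interaction compendia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring agreement between drug-drug interaction compendia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ddiconcord)
```

## The problem

Drug information resources (DIRs) such as the BNF, the ANSM interaction
Thesaurus and Micromedex each maintain a catalogue of drug-drug
interactions (DDIs) with severity grades, evidence (substantiation)
grades, and free-text clinical-management advice. Because these catalogues
are compiled independently, they disagree — on which drug pairs interact
at all, on how severe an interaction is, and on what a prescriber should
do. `ddiconcord` quantifies that disagreement. This vignette documents the
model and the design decisions behind each stage, what the synthetic data
generator does and does not emulate, and the numerical conventions used
throughout.

## The unit of comparison: canonical pairs

All set comparisons operate on *canonical pairs*: unordered pairs of
normalised ingredient identifiers. Three cleaning rules produce them:

* **Name normalisation.** Raw names map through a supplied table to an
  ingredient concept, or to `UNMAPPED` (names too vague to resolve) or
  `NON_DRUG` (herbs, foods, beverages, tobacco, lab tests). The lookup is
  total: names absent from the table count as `UNMAPPED`. Rows with any
  non-ingredient member are dropped and tallied in the exclusion report.
  The mapping table is authoritative — there is deliberately no fuzzy
  matching, so a given input always cleans identically.
* **Class expansion.** Rows stated at drug-class level are replaced by one
  row per class member *before* normalisation, inheriting the row's
  ratings and advice. A class can appear on either or both sides (both
  sides give the Cartesian product of members).
* **Canonical ordering.** The two member names are sorted
  case-insensitively under a fixed byte-wise collation, so (D1, D2) and
  (D2, D1) coincide and results cannot depend on the session locale. Rows
  whose two members normalise to the *same* ingredient (e.g. two salts of
  one drug listed against each other) are dropped as self-pairs and
  counted separately — the sources are silent on this case, and a
  self-interaction is meaningless at ingredient level.

Duplicate rows for one canonical pair merge into a single record. The
record keeps the full set of observed severity ranks; the *resolved*
severity is the most severe ("where multiple ratings exist, keep the
highest"). Severity levels are ranked in each resource's displayed order
with rank 1 the most severe, so "highest severity" is the minimum rank.
One consequence worth making explicit: the BNF's *Unknown* level ranks
4th (least severe) because the source displays it last, even though it
semantically means "outcome unpredicted". Evidence conflicts on merge
resolve to the strongest level (Study > Anecdotal > Theoretical;
Established > Theoretical > Probable); unrated duplicates contribute their
provenance but never override a rated one. Severity vocabularies are
closed: an unknown label is a hard error rather than a silent drop,
because a label outside the scheme always indicates an upstream data
problem.

## Listing, severity and evidence agreement

Listing agreement is described by the seven exclusive regions of the three
pair sets (`venn_partition()`), directional coverage rates
$100\,|A \cap B|/|A|$ and Jaccard indices $|A \cap B|/|A \cup B|$.
Pairwise intersection counts are reported in both conventions — inclusive
and exclusive of the triple region — and labelled as such, since published
tables usually print the inclusive form. A second partition restricted to
pairs whose both members lie in the three-way *ingredient* intersection
(`ingredient_restricted_partition()`) separates "the resource does not
cover this drug" from "the resource covers both drugs but not this
interaction".

Severity agreement is a per-level cross-tabulation: for each severity
level of a row resource, the shared pairs are subcategorised by the other
resource's levels, with an explicit *Not found* column for pairs the other
resource does not list; row percentages are shares of the row-level total.
Evidence agreement works the same way between the resource that rates only
part of its catalogue (unrated records form an explicit `"none"` level —
dropping them would hide half the picture) and the resource that rates
everything, with both directional coverage rates per cell. *Critical*
overlap restricts the comparison to each resource's configured critical
levels; criticality is configuration, not code, and the shipped defaults
(BNF *Severe*; Thesaurus *Contraindicated*, *Not recommended*; Micromedex
*Contraindicated*, *Major*) can be overridden.

No significance testing or chance-corrected agreement (kappa) is computed:
the statistics are deliberately descriptive, matching how such comparisons
are reported.

### Checking published arithmetic

`verify_printed_statistics()` re-derives every percentage that published
three-compendium comparisons print alongside their counts, using the
package's own arithmetic on the shipped reference counts, and compares at
two-decimal precision. Because the source tables demonstrably mix half-up
rounding and truncation (e.g. 41 713/65 446 = 63.7362% printed as 63.73),
a value matching either presentation counts as reproduced. A few published
values are *not* derivable from the published counts — the Micromedex and
Thesaurus sides of two joint-critical coverages, whose implied
denominators match no published quantity, and two BNF severity shares
whose level counts do not sum to the published BNF total. These rows are
flagged `checked = FALSE`, with both candidate denominators shown, rather
than silently passed or failed.

## Advice annotation

Clinical-management texts are annotated with up to nine advice categories
(avoid, use with caution, space dosing times, wash-out, monitor, adjust
dose, modify administration, use alternative, discontinue). Small corpora
are expected to be labelled manually and consumed from a label file; the
automated path exists for corpora too large to label by hand.

**Pre-processing.** Texts are lower-cased; every drug name from a supplied
lexicon is replaced by the common token `DRUG` (longest names first, at
word boundaries, so multi-word names are replaced whole); sentences are
split at `.`/`!`/`?` boundaries; tokens are split on non-alphanumeric
boundaries with no stop-word removal; and tokens are reduced to Porter
(1980) word roots. The sentence splitter is a deliberate simplification —
it has no abbreviation model — which is acceptable here because compendium
management texts are short imperative sentences; texts with heavy
abbreviation use would need a better splitter. Stop words are retained
because the tf-idf damping already down-weights corpus-universal words.

**Encoding.** A sentence is a vector of
$\mathrm{tfidf}(w,s) = \mathrm{tf}(w,s)\cdot\log\!\big(N/(\mathrm{df}(w)+1)\big)$,
with $\mathrm{tf}$ the within-sentence relative frequency, $N$ the corpus
sentence count and $\mathrm{df}(w)$ the number of sentences containing
$w$. The logarithm is natural by default (configurable); note the $+1$
damping gives corpus-universal words a small *negative* weight rather
than zero, which is intentional and matches the formula as stated.

**Classification.** One binary linear-kernel SVM per category
(`e1071::svm`, no feature scaling). Class imbalance is handled by giving
each class a fixed total misclassification budget `cost`, spread over its
members: per-class libsvm weight $\mathrm{cost}/(2 n_c)$. This is
inverse-class-frequency weighting with the property that duplicating the
training set leaves the solution unchanged (per-sample schemes double the
effective penalty instead). The default `cost = 1000` corresponds to
roughly unit per-sentence cost at the few-hundred-sentence corpus sizes
this tool targets, keeping clearly keyword-separable corpora separated
while the margin term still regularises genuinely ambiguous sentences.

**Threshold selection.** Each sentence is scored by a model trained on all
other sentences (leave-one-out; folds that lose a class entirely are
skipped with a warning, and constant labels yield an empty score list).
Candidate thresholds are the midpoints between consecutive sorted unique
scores plus $\pm\infty$ sentinels. Among operating points with estimated
PPV at or above the floor (default 0.80), the selected threshold has
maximum sensitivity; ties break toward higher PPV, then higher threshold
(the most conservative realisation of the same confusion counts). If no
point qualifies, the classifier is REJECTED — a first-class outcome, not
an error: some categories are simply not learnable from a given corpus,
and their sentences should then be labelled manually. Decision scores, not
calibrated probabilities, feed this analysis; calibration is out of scope.
Annotation applies each ACTIVE classifier independently (a sentence can
carry several labels), records with no positive decision are flagged
no-advice, and record-level labels are the union over the record's
sentences. Hold-out validation reports PPV, sensitivity and F1 per
category, with undefined metrics reported as not-applicable, never as 0.

## The synthetic-data generator

`sim_config()` describes a complete synthetic study. Its defaults are
fixed study conditions, not tuning knobs:

* `venn_region_sizes = c(29, 19, 46, 8, 7, 5, 7)` — the published
  three-compendium exclusive regions scaled by 1/1000 and rounded, so the
  synthetic study has the same *shape* of disagreement at desk scale
  (121 pairs, 60 ingredients).
* Severity and evidence distributions — the published per-resource rating
  proportions (e.g. BNF 24.56% *Severe* ... 65.47% *Unknown*; Micromedex
  evidence 8.73/70.91/20.36; the BNF-style resource leaves 69.34% of rows
  unrated; the Thesaurus-style resource has no evidence field).
* Rates with no published value, chosen once as realistic:
  `salt_variant_rate = 0.1` (a salt-suffixed duplicate row pair for ~10%
  of rows), `class_row_rate = 0.1` (of eligible row groups collapsed into
  a class row, Thesaurus-style resource only), `advice_noise_rate = 0.2`
  (filler sentences with no advice), `multi_label_rate = 0.25` (advice
  texts carrying two categories).

Every random artifact (universe, severities, evidence, advice, salt
injection, order swapping) draws from its own stream seeded by hashing the
master seed with the stream label, so adding an artifact never perturbs
the others and identical configurations are byte-identical. Ingredient
names are synthetic tokens (`drug0001`...), never real drug names.

The generator emulates the *observable structure* of compendium extracts:
overlap structure (exactly realised, enabling exact round-trip tests),
name variants that collapse under mapping, class rows that expand back to
exactly their source pairs, categorical rating draws, swapped pair order,
and template advice sentences with known multi-label ground truth and
category-specific vocabulary. It does not emulate real pharmacology,
realistic nomenclature beyond salt suffixes, correlated ratings between
resources, or the messy free text of real management advice. Passing the
round-trip and recovery tests therefore demonstrates that the pipeline's
mechanics are correct — not that real-world classifier performance will
match the synthetic recovery rates, since real sentences share vocabulary
across categories far more than templates do.

## Numerical conventions and problem sizes

* All internal computation is full precision; percentages are rounded half
  away from zero to 2 decimals only at presentation (`round_half_up()`),
  since banker's rounding disagrees with how compendium reports print.
* Deterministic tie-breaks everywhere: byte-wise collation for pair
  ordering and table sorting; the threshold tie-break above; merged advice
  texts kept in input (provenance) order.
* Degenerate inputs are defined, not accidental: empty tables are valid
  (empty partitions result), coverage of an empty reference set and the
  Jaccard index of two empty sets are errors, an empty severity set cannot
  be resolved, and an all-degenerate leave-one-out returns an empty score
  list.
* Test problem sizes are chosen for tight independent oracles: merge
  checks against a brute-force group-by at up to 50 rows; Venn partitions
  against region-by-region enumeration at up to 80-element universes;
  leave-one-out against naive retraining at 24 sentences; classifier
  recovery on a 400-sentence training corpus with a 100-sentence hold-out;
  severity-distribution recovery by chi-squared goodness of fit at 7300
  pairs (with class rows disabled there, because class members share one
  severity draw — correct generator behaviour that would violate the
  test's independence assumption, not a generator defect).

## Interfaces

The exported functions are the interface; `run_pipeline()` ties them
together from a plain list or YAML configuration and persists long-format
CSV/JSON reports, and `scripts/acceptance.R` (repository root) recomputes
the published-count checks and synthetic recovery measures end to end.
Figures are deliberately not produced by the pipeline: every report is a
table from which a figure can be drawn, and no computation consumes a
figure.

## Known limitations

* The name mapping is consumed, not created: mapping raw names to
  ingredient concepts (the hard terminology problem) is upstream of this
  package.
* The sentence splitter and tokeniser are simple pattern rules
  (no abbreviation handling, no hyphen model); the Porter stemmer is
  English-only — corpora in other languages must be labelled manually.
* Rejection thresholds and class weighting assume a few hundred labelled
  sentences; very small labelled sets will reject most classifiers, by
  design.
* Agreement statistics are descriptive; no uncertainty quantification is
  attached to them.
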