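---
title: "Scoring model and design notes for the laboratory safety instrument"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring model and design notes for the laboratory safety instrument}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lmtscore)
```

## The instrument

`lmtscore` implements a standardized semi-quantitative assessment of
laboratory safety and biosecurity in (veterinary) laboratories. The
instrument is a questionnaire of 98 *subcategories* — single scored
questions — grouped into 20 *categories* of related practices across 4
*areas*: administrative controls, operational controls, engineering
controls, and personal protective equipment (PPE). Each subcategory is
scored on a four-level rubric in which level 4 describes the optimal
practice and level 1 the most basic level of activity or awareness, with
a *Not applicable* (N/A) escape for questions that genuinely do not apply
(for example BSL-3 containment items in a BSL-2 facility). The instrument
definition is data, not code: it is a versioned JSON schema document
(`load_taxonomy()`), and the standard 98-question module ships with the
package (`builtin_lmt_s()`). Only one of the 98 rubrics has ever been
published in full (Disposable glove usage); the remaining 97
subcategories carry clearly labelled placeholder names and rubric text —
inventing their content would be fabrication, and every function treats
rubric text as opaque data, so nothing downstream depends on it.

## The score

A scope (a category, an area, or the whole questionnaire) containing
answered levels $x_1, \dots, x_n \in \{1,2,3,4\}$ scores

$$\mathrm{percent} = 100 \times \frac{\sum_i x_i}{4n},$$

the percentage of the optimum: a laboratory answering 4 everywhere scores
100%. N/A responses are removed from numerator and denominator. Every
aggregate weights subcategories equally — the overall score is the
applicable-count-weighted mean of category scores, *not* their plain
mean.

**Blank policy.** The published score definition never states whether
unanswered questions penalize the score. Two policies are therefore
first-class and recorded in every report:

* `exclude` (default): blanks are left out of scoring entirely, so a
  defined percent always lies in [25, 100] (the floor is an all-1
  scope). Incompleteness is reflected only in the confidence score.
* `blank_as_zero`: a blank contributes 0 to the numerator and one item
  to the denominator, giving the [0, 100] range. Pilot summary tables
  report regional minima well below 25%, which are unreachable under
  pure exclusion — evidence that a blank-penalizing reading existed in
  the field — so the variant is provided without asserting which rule
  the original spreadsheet used.

A consequence worth stating: under `exclude`, marking a blank question
N/A changes no score (exact neutrality); under `blank_as_zero` it removes
a zero-contributing item from the denominator, so scores can only move
up. The test suite asserts exactly these two properties.

**Undefined scopes.** A scope with zero applicable responses has no
score. It is carried as `NA`, rendered `"N/A"` in tables, breaks the
polygon on radar axes, and is excluded lab-wise from cohort statistics —
it is never silently coerced to 0.

## Confidence and radar bands

The *confidence score* is the completion percentage: 100 × (non-blank
responses) / 98, with N/A counting as completed (the assessor considered
the question). Completion in [0, 70) is ranked low confidence, [70, 90)
medium, and [90, 100] reliable. The published thresholds are printed as
touching integer ranges (0–69, 70–89, 90–100) with no decimals;
lower-inclusive half-open intervals are the one convention that
reproduces them at every integer input, and fractional boundary behavior
(69.99 → low, 70.0 → medium) is a package decision, frozen in tests.

Scores are ranked into five 20-point *radar bands*
($\lfloor p/20 \rfloor$, top band closed so 100 ↦ band 4) used to shade
the radar chart from red (bottom band) to green (top band). Band colors
are a styling choice; the five 20-point intervals are not.

**Rounding.** Full precision is kept everywhere internally; one decimal
is applied only at presentation, matching the precision of published
scores such as 43.8 and 55.6.

## Comparison and concordance

`compare_assessments()` aligns ≥ 2 assessments of one laboratory on the
same instrument and policy and reports per-scope series plus deltas
against the first (baseline) assessment; consecutive deltas are
derivable by the caller. The workbook format holds at most 3
assessments — a format limit, not a model limit, so the library accepts
more and the workbook writer truncates with a warning only when asked.
A delta is defined only where both sides are defined.

No numeric statistic was ever published for the claim that external and
internal assessors ranked laboratories consistently; `concordance()`
therefore reports deliberately simple quantities — exact-agreement
proportion and the histogram of absolute level differences over items
answered by both — and flags nothing beyond them.

## Cohort aggregation

`aggregate_reports()` produces per-scope mean, sample SD (n−1
denominator — the published "(±14.2)" does not state the estimator;
sample SD is the conventional cohort choice), min and max over
laboratories with a defined score, serialized in the published cell
grammar `mean (±sd); range lo–hi%`. Mean and SD print to one decimal;
range endpoints print as integers, matching the published table layout.
"Largest discrepancies between laboratories" was described without a
formula; the package uses inter-laboratory SD (more robust than range),
records the metric in the output, and breaks ties by instrument order so
rankings are reproducible. Cohort output is anonymous unless explicitly
`named = TRUE`, mirroring the confidentiality of the assessment process.

## Gap analysis

The four rubric levels form a progression: each increasing level states
the additional practice required to advance. `gap_report()` emits, for
every answered question below level 4, the next level's practice text,
ordered weakest category first (ascending category percent, Undefined
categories last — they carry no evidence of weakness, only of absence —
then instrument order). Blank questions are listed in a separate
"unassessed" section pointing at the level-1 practice ("establish
baseline") rather than dropped: the instrument doubles as a self-help
tool and hiding unassessed items would undermine that use.

## Interchange formats

JSON (a versioned envelope) is the canonical machine format; a flat CSV
(`subcategory_id,response`) carries the response payload only. The
six-sheet workbook mirrors the instrument's spreadsheet layout — index,
user guideline, laboratory information, safety module questionnaire (one
row per subcategory, up to 3 assessment columns), safety summary
(regenerated, never parsed back), rights — but is implemented as a
documented plain-text multi-sheet file: no spreadsheet writer is
available in the supported dependency set, the original binary layout
was never published cell-by-cell, and a text format gives byte-stable
output for free. The N/A marker in CSV and workbook cells is the literal
string `NA` (case-insensitive); an empty cell is a blank. Every reader
rejects out-of-domain values with a located error (sheet/row/column)
rather than coercing.

## Synthetic data

No pilot assessment data is public, so the generator
(`generator_config()`, `generate_assessment()`, `generate_cohort()`) is
the package's only source of full assessments. Each subcategory is drawn
independently: blank with probability `blank_rate`, N/A with `na_rate`,
otherwise a level from `level_distribution` (defaults: uniform levels,
no blanks, no N/A — the neutral stated world; the expected overall under
the uniform default is $100 \times 2.5/4 = 62.5$, which the acceptance
suite recovers by simulation). Cohort members derive their seeds from
the master seed by a documented rule (`seed + k·7919 mod 2³¹−1`) so any
single laboratory is regenerable. The generator deliberately does *not*
emulate item correlation, assessor bias, or laboratory-tier effects —
the only structure available is a per-area level distribution override —
so a green property test establishes arithmetic correctness of the
pipeline, not realism of the response model.

`assessment_with_overall()` deterministically solves (brute force over
number-answered × level-sum) for a response vector whose overall score
is closest to a requested value; it exists to construct exemplars that
reproduce published score progressions (43.8 → 55.6) without inventing
data.

## Numerical and degenerate-input choices

* Percent comparisons in tests use exact arithmetic where forced
  (100 × 10/16 = 62.5) and `all.equal` tolerance elsewhere.
* `scope_percent(character(0))` and all-N/A scopes are Undefined, not 0
  and not an error.
* An empty assessment is legal: completion 0, confidence low, every
  scope Undefined under `exclude`.
* Duplicate response rows, unknown subcategory ids, rubric levels
  outside 1..4 and malformed envelopes are hard errors naming the
  offending node; taxonomy validation (`validate_taxonomy()`) instead
  returns one finding per violation so a schema author sees everything
  at once.

## Known limitations

97 of 98 rubrics are placeholders; gap reports over the built-in
instrument are structurally correct but textually generic. The workbook
is a faithful reconstruction of the described 6-tab layout, not a
bit-level clone of the original file. Regional pilot values (means, SDs,
figure polygons) derive from confidential assessments and are not
reproduced anywhere in the package, its tests, or its acceptance
report.
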