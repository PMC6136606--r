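# lmtscore

Scoring engine for a standardized laboratory **safety and biosecurity**
assessment instrument — the safety module of the FAO Laboratory Mapping
Tool family. The instrument queries 98 laboratory practices
(*subcategories*) grouped into 20 *categories* across 4 *areas*
(administrative controls, operations, engineering, PPE); each question is
scored on a four-level rubric (4 = optimal practice, 1 = most basic) with
a *Not applicable* escape. The package is for laboratory assessors,
biosafety officers, and national/regional programme managers who need
reproducible scoring, progress tracking, and cohort summaries from such
assessments.

## The model

A scope (category, area, or the whole questionnaire) with answered
levels $x_1,\dots,x_n \in \{1,2,3,4\}$ scores a percentage of optimum

$$\mathrm{percent} = 100 \times \frac{\sum_i x_i}{4n}$$

with N/A items removed from numerator and denominator, so an all-4
laboratory scores 100%. Unanswered (blank) questions are excluded under
the default `exclude` policy, or counted as zeros under `blank_as_zero`
(both are first-class; see the vignette for why). Alongside the scores
the engine reports:

* a **confidence band** from the completion percentage — low [0, 70),
  medium [70, 90), reliable [90, 100];
* a **radar band** per scope — five 20-point rankings
  ($\lfloor p/20\rfloor$, 100 in the top band) that color the
  radar-style chart;
* **comparisons** of 2+ assessments (baseline vs follow-up, external vs
  self) with per-scope deltas, **gap reports** surfacing the next rubric
  level for every sub-optimal answer, and **cohort summaries**
  (mean (±sd); range lo–hi% per scope, discrepancy ranking by
  inter-laboratory SD).

## Worked example

```r
library(lmtscore)

t <- builtin_lmt_s()   # the packaged 4-area / 20-category / 98-question instrument

# a seeded synthetic assessment (no real assessment data is public)
cfg <- generator_config(seed = 7,
                        level_distribution = c(0.15, 0.35, 0.3, 0.2),
                        blank_rate = 0.05, na_rate = 0.05)
a <- generate_assessment(cfg, t, label = "baseline-2017")
print(render_summary_tables(score_assessment(a, t, policy = "exclude")))
```

```
scope                                                   baseline-2017
Overall                                                          65.2
Administration                                                   53.8
Operations                                                       61.3
Engineering                                                      71.8
Personal protective equipment (PPE)                              70.8
  General                                                        56.2
  ...
  PPE disposal                                                   75.0
baseline-2017: completion 92.9%, confidence reliable
```

The overall score 65.2 means the laboratory reached 65.2% of the
optimum (all-4) benchmark over the questions it answered; 92.9% of the
98 questions were completed, so the assessment is ranked *reliable*.
Progress tracking works the same way:

```r
base <- assessment_with_overall(43.8, t, "baseline")
foll <- assessment_with_overall(55.6, t, "follow-up")
cmp  <- compare_assessments(list(base, foll), t)
print(cmp)
#> <lmt_comparison> 2 assessments (policy: exclude)
#>   baseline: overall 43.8  completion 99.0% (reliable)
#>   follow-up: overall 55.6  completion 68.4% (low)
#>   delta follow-up vs baseline: +11.8
render_radar(cmp$reports, "progress.png", level = "area")  # blue vs red polygons
```

A command-line interface wraps the same operations
(`exec/lmtscore score|compare|aggregate|gaps|convert|report|generate|validate`),
reading/writing the JSON, CSV and 6-sheet plain-text workbook
interchange formats.

## Layout

* `R/` — taxonomy model and validation, scoring engine, comparison,
  aggregation, gap analysis, I/O formats, radar/table rendering,
  synthetic-data generator, CLI.
* `inst/extdata/lmt_s.json` — the built-in instrument schema (the one
  published rubric in full; 97 labelled placeholder rubrics).
* `vignettes/instrument-scoring.Rmd` — scoring model, conventions, and
  design rationale.
* `tests/testthat/` — unit, property and acceptance suites.
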