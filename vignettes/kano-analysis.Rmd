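---
title: "Kano demand analysis: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Kano demand analysis: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kanodemand)
```

## The measurement model

A Kano survey asks, for every service attribute, a *functional* question
(how the respondent would feel if the attribute were provided) and a
*dysfunctional* question (how they would feel without it), both on the same
five-level scale coded 1–5 in the order *like* / *must be* / *neutral* /
*live with* / *dislike*. The pair of codes is looked up in the 5×5
evaluation table:

```{r}
kano_evaluation_table()
```

The table is a packaged constant, not code: `classify_response()` and
everything downstream accept a variant grid, and the default is validated
in the test suite by its cell census (2 Q, 3 A, 1 O, 3 M, 9 I, 7 R) and by
the round-trip property with `valid_pairs_for()`, its inverse image.
Liking both presence and absence, or disliking both, is internally
contradictory (Q); preferring absence is a reverse (R) preference. Neither
contributes to the quality categories, so both are excluded from all index
denominators. In the bundled case study every attribute's M/O/A/I counts
sum to the full sample of 436, i.e. no R or Q responses remained; the
pipeline nevertheless supports nonzero R/Q and per-attribute missingness
(dropped pairwise, so denominators may differ across attributes).

## Per-attribute statistics

With frequencies $f_M, f_O, f_A, f_I$ and $N$ their sum:

* `better_index()` $= (f_A+f_O)/N \in [0,1]$ — share of respondents for
  whom the attribute can create satisfaction.
* `worse_index()` $= -(f_O+f_M)/N \in [-1,0]$ — share dissatisfied if it
  is absent, stored and reported with the negative sign; the magnitude is
  a display choice in the quadrant plot. Two conventions are implemented
  because the literature typesets the numerator both ways: `"berger"`
  (O + M, the default) and `"attractive_must"` (A + M). The bundled
  reference table is arithmetically consistent with `"berger"` on every
  row that is consistent at all (18 of 23), and with the alternative on
  only one, which settles the default empirically; the audit that
  established this is `compare_reference()` and runs in the test suite.
* `total_satisfaction()` $= (f_M+f_O+f_A)/N$ — the share classifying the
  attribute as any of the three quality categories.
* `category_strength()` $=$ (largest − second-largest of
  $f_M, f_O, f_A$) $/N$ — decisiveness of the modal classification.
  Published tables rarely define this column; the runner-up-margin rule
  over the three quality categories is adopted here because it reproduces
  all 23 cells of the bundled reference exactly, which the test suite
  verifies. It is an inference, clearly: a different rule that happens to
  agree on these 23 rows cannot be excluded.
* `importance_degree()` $= (5f_M+3f_O+1f_A+0f_I)/N \in [0,5]$ — the
  frequency-weighted importance score with the conventional 5/3/1/0
  weights, satisfying TSI ≤ ID ≤ 5·TSI.
* `classify_attribute()` — argmax over the four frequencies. Ties do not
  occur in the case study but the rule must be total; the default
  preference order M > O > A > I resolves ties toward the most
  conservative (least dismissible) quality and is configurable.

Survey-level aggregation (`summarize_survey()`) uses the *unrounded*
importance degrees for the mean, and strict inequality for the
above-average list — the natural reading of "above average", and the pair
of choices under which the case study yields a mean of 2.25 with exactly 12
attributes above it.

## Rounding and reporting

Internal values are exact fractions; only the reporting layer rounds.
Printed tables in this field use commercial rounding, so `round_half_up()`
rounds ties away from zero (2.705 → 2.71), where base `round()` would go to
even. Better/Worse are written as signed two-decimal percentages,
the other three indices as plain two-decimal values, mirroring the usual
table layout; JSON output keeps full-precision fractions.

## The better–worse plane

`quadrant_assign()` places attributes at (|Worse|, Better) and cuts the
plane at configurable thresholds, defaulting to the cross-attribute means
of the two coordinates — the standard choice when no dividing lines are
prescribed. A coordinate equal to its threshold counts as "high", which
makes the partition exhaustive and exclusive for any threshold pair (a
property test exercises random thresholds). The thresholds used are echoed
in the output for audit. No correspondence between plot quadrants and Kano
categories is asserted: the two classifications answer different questions.

## Reliability statistics

`cronbach_alpha()` uses the variance-ratio definition with the sample
(n−1) variance convention; the choice is stated because population-variance
implementations shift α slightly at small n. α is invariant under item
location shifts but not under rescaling a single item, which is tested.
`kmo_overall()` computes the Kaiser–Meyer–Olkin measure from the anti-image
partial correlations; `bartlett_sphericity()` uses the chi-square
approximation $-(n-1-(2k+5)/6)\log\det R$ on $k(k-1)/2$ degrees of freedom.
Pearson correlations on the ordinal codes are used throughout — the common
practice for five-level Likert items; polychoric variants are out of scope.
`reliability_report()` computes α per dimension and pooled over all items
of a polarity (labelled `"overall"`), separately for the functional and
dysfunctional banks, and KMO/Bartlett on the combined two-bank matrix after
listwise deletion. Published α values for any particular survey cannot be
reproduced without the raw responses; the statistics are validated instead
by closed forms (duplicated items give α = 1; two items give KMO = 0.5
exactly) and by simulation against the latent-factor generator.

## What the synthetic generators emulate — and what they do not

Three generators, each with a mandatory seed (no hidden global RNG state;
`withr::with_seed()` restores the caller's RNG):

* `generate_from_counts()` realises exact per-attribute category counts:
  category labels are assigned to respondents in seeded random order and
  each label is realised as an answer pair drawn uniformly from that
  category's cells of the evaluation table (or a fixed canonical cell).
  Because every downstream statistic depends on the answers only through
  the category frequencies, `kano_tabulate()` after generation returns the
  input counts exactly for any seed — the round-trip identity that makes
  the case-study reproduction end-to-end rather than a lookup.
* `generate_mixture()` draws each respondent × attribute category from a
  per-attribute probability vector, for recovery and robustness studies
  where sampling noise matters.
* `generate_likert_factor()` simulates the within-dimension correlation
  that reliability statistics measure: one standard-normal factor per
  dimension, item $j$ = loading·factor + $\sqrt{1-\text{loading}^2}$·noise,
  discretised at symmetric cut points (−1.5, −0.5, 0.5, 1.5), chosen so a
  standard-normal latent spreads mass over all five levels.

Deliberate simplifications: respondents are independent across attributes
(no per-respondent acquiescence or random effect), category frequencies
carry no demographic structure, and the Likert generator's single-factor,
equal-cutpoint structure is far tidier than real questionnaire data.
Passing tests therefore demonstrate correctness of the *computations* on
data with the assumed structure, not robustness to interviewer effects,
differential item functioning or non-independent attributes.

## Problem sizes and tolerances in the tests

The simulation-backed checks use sizes chosen to keep sampling error well
inside their margins: α on latent-factor data uses n = 2000–4000 with
k = 4–6 items; the Bartlett null check averages 100–200 replicates of
n = 200, k = 4 (mean statistic within ~1 of its dof of 6); mixture recovery
uses a 0.5-dominant category at n = 1000 over 200 seeds (recovery ≥ 99%);
law-of-large-numbers checks use n = 10000 with ±3 binomial-SD bands. Exact
checks (table census, round trips, case-study reproduction) use no
tolerance beyond two-decimal reporting precision.

## Known limitations

* The category-strength rule and the default Worse convention are
  empirically inferred from agreement with published tables, as described
  above.
* Thirteen Better/Worse cells of the bundled reference table disagree with
  its own counts (several by exactly one respondent, suggesting
  transcription slips); the package reproduces the formula-consistent
  values and reports the discrepancy rather than matching the printed
  cells.
* No inferential statistics (confidence intervals or tests on index
  differences) are provided; the indices are descriptive.
* Ordinal codes are treated as numeric in the reliability module.
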