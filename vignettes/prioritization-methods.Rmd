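---
title: "Methods: weighted-sum prioritization of Olympia oyster estuaries"
author: "olyprior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: weighted-sum prioritization of Olympia oyster estuaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(olyprior)
```

## The scoring model

The unit of analysis is the estuary; sub-basins of the two largest systems
on the coast (the Salish Sea and San Francisco Bay) are delineated and
treated as independent estuaries, and the package never aggregates records
across a `parent_system`. Each estuary carries an ordinal score
$v_{ec} \in \{0, 1, 2\}$ on each of fourteen criteria — four ecological
(recruitment limitation, local extinction risk, post-settlement mortality,
isolation) and ten social, regulatory and infrastructural — plus an optional
certainty annotation $k_{ec} \in \{1, 2, 3\}$ on each score.

An index is a named weight vector $w$ of strictly positive integers over a
criterion subset $C$, a (possibly empty) veto subset $O \subseteq C$, and a
rational threshold $t \in (0, 1]$. The index score is

$$S(e) \;=\; \begin{cases}
0 & \text{if } \exists\, c \in O:\ \tilde v_{ec} = 0\\[2pt]
\dfrac{\sum_{c \in C} w_c\, \tilde v_{ec}}{2 \sum_{c \in C} w_c} & \text{otherwise,}
\end{cases}$$

where $\tilde v_{ec}$ is the *effective* value: the assigned score, or 0
when the score is missing. The estuary is a priority when $S(e) \ge t$.

Assumptions worth making explicit:

* **Fixed polarity.** Higher always means "better candidate for aquaculture
  investment"; the default registry contains no reverse-scored criterion, so
  none are supported there.
* **Additivity.** Criteria contribute independently; the only interaction in
  the model is the veto rule.
* **Missing scores as zero.** This is conservative by construction — an
  estuary can only move up as knowledge accumulates. The
  `n_missing_weighted` column of every result row quantifies how much of a
  score rests on this convention.
* **Certainty is metadata.** The 1–3 certainty levels never enter the score;
  they are consumed only by the sensitivity module.

## Eligibility

Scoring a data-poor estuary at 0 everywhere would make it look like a bad
site rather than an unknown one. Records with **no information on criteria
1–3** are therefore excluded before scoring and reported separately. The
phrase "no information on the first three criteria" admits two readings, and
nothing in the model fixes one: `eligibility_rule()` defaults to
`all_missing` (dropped only when all three are unscored), with
`any_missing` one argument away. We default to `all_missing` because it is
the literal reading of "no information" and the less aggressive filter;
users comparing against a concrete dataset with a known eligible count can
flip the mode if their numbers disagree.

## Exact threshold arithmetic

The attainable scores are ratios of small integers, and the priority rule is
boundary-inclusive ($\ge$), so a score of exactly $11/22$ against a
threshold of $0.50$ must classify as priority every time. Binary floating
point cannot promise that in general, so the package never compares floats
to thresholds: thresholds are parsed from decimal or fraction text to exact
integer rationals ($0.50 \to 1/2$, $0.6 \to 3/5$), and classification is the
integer comparison $\mathrm{raw} \times t_\mathrm{den} \ge
\mathrm{max} \times t_\mathrm{num}$. The numeric `score` column exists for
display and downstream numerics only. For the same reason weights are
restricted to positive integers and configuration files supplying
fractional weights are rejected at load time. A related presentation choice:
summaries report a "high but not maximal" band as $0.7 < S < 1$ with a
*strict* lower bound, again computed on raw integers ($10\,\mathrm{raw} >
7\,\mathrm{max}$), keeping the band disjoint from the exact-maximum count.

Missing values inside a veto criterion trigger the veto: the missing-as-zero
rule makes the effective value 0, and the veto fires on a zero. This is the
conservative composition of the two rules — an estuary with unknown
consumption safety is not recommended for harvest — and the missing-count
column flags such records for the user.

## Tie-breaking and degenerate inputs

Rankings order by score descending, then by fewer missing weighted criteria
(equal scores built on more data rank higher), then by estuary name — a
total, deterministic order, so repeated runs and platforms agree byte for
byte. Empty tables, empty eligible sets, records with every score missing,
and header-only CSV files are all legal inputs that produce empty-but-valid
outputs rather than errors; duplicate estuary names and off-scale values are
hard errors. Report files render scores to two decimals, but display
rounding can never change a classification because classification never
reads the rendered value.

## Parameters that matter

| parameter | default | units / range | why |
|---|---|---|---|
| index weights | Table of four defaults | positive integers | stakeholder-consensus importance; integer to keep arithmetic exact |
| `threshold` | 0.50 | fraction of max score | transparent "majority of weighted criteria met" rule |
| eligibility `mode` | `all_missing` | — | literal reading of "no information"; configurable |
| `flip_probabilities` | 0.30 / 0.10 / 0.02 (certainty 1/2/3), 0.30 unannotated | probability per draw | orders certainty levels; configuration constants, not findings |
| `weight_jitter_range` | 1 | integer weight steps | smallest perturbation that respects integer weights |
| `n_draws` | 500 | draws | stabilizes frequencies to a few percent at pipeline cost of seconds |

## Sensitivity analysis

The scoring framework annotates certainty but does not propagate it; the
sensitivity module supplies that propagation as clearly labelled machinery.
Three perturbation kinds re-run the full pipeline and record each eligible
estuary's priority flag per draw:

* `score_resample` — each assigned score flips, with a certainty-graded
  probability, to an *ordinally adjacent* value (0 and 2 move to 1; 1 moves
  up or down with equal probability). One-step expert mis-scoring is the
  plausible error mode for an ordinal elicitation; larger jumps would imply
  an error model nothing in the data supports. Missing values are never
  resampled, and eligibility is never perturbed.
* `weight_jitter` — each weight moves by an integer step in
  $\pm$`weight_jitter_range`, floored at 1.
* `leave_one_criterion_out` — deterministic: every weighted criterion of
  every index is removed once and the maximum rescaled.

Reports contain per-estuary priority frequencies, always/never lists, and
the mean Jaccard similarity between each draw's priority set and the
baseline (defined as 1 when both sets are empty). All randomness flows from
the scheme's single seed, which is saved and restored around the run, so
identical inputs give identical reports. Any stability claim should be
quoted together with the flip probabilities that produced it — the numeric
meaning of the certainty stars is configuration, not data.

## The synthetic generator

`generate_table()` emulates the statistical shape of a range-wide scoring
table: 66 records split across regions in north-to-south order
(BCC 15%, WA 30%, OR 12%, CA 33%, BCM 10% — the sub-basin-rich Washington
and California coasts carry most records), per-criterion missingness
elevated at the range edges (35% in British Columbia, 45% in Baja
California, 8–12% elsewhere) where estuaries are least studied, a 40%
rate of records missing all three core criteria (matching the magnitude of
exclusions a real screen produces), ordinal scores drawn from a mildly
low-shifted distribution (0.35 / 0.35 / 0.30), and a certainty draw on
every assigned score. These defaults were chosen once, on the grounds
above, and are not tuned.

What the generator deliberately does **not** emulate: correlations between
criteria (safe-to-eat and bivalves-farmed surely co-vary in real data — no
published correlation structure exists to calibrate one, and independence
suffices to exercise the pipeline), geographic coordinates, and any real
estuary's identity or scores. Passing tests on generated tables therefore
demonstrates the correctness of the *machinery*, not distributional claims
about real estuaries.

`generate_benchmark_fixture()` is different: a direct construction, not a
sampler. Ten records are engineered criterion-by-criterion so that a default
run yields 40 eligible of 66, ten ecological priorities — two at exactly
1.0, three strictly inside $(0.7, 1)$, one sitting exactly on the $11/22$
boundary — and 5 / 4 / 4 of the ten meeting the community-restoration,
community-harvest and commercial-production thresholds, with the harvest
failures including genuine veto cases. The unconstrained entries (filler
scores, certainty draws) come from the seeded generator, so the count
structure holds for every seed while each seed yields a byte-identical
table. The fixture encodes only this count structure; its names are
synthetic by construction.

## Problem sizes

The shipped tests run the full pipeline on tables of 10–66 records, check
oracle equivalence of the index algebra on 1000 random records, goodness of
fit of the generator on a 5000-record table, and sensitivity stability over
20 seeds at 500 draws on 10-record tables — sizes chosen so the whole suite
completes in well under a minute while every claim is exercised at scale
comparable to the real use case (a coast-wide table is 66 rows).

## Known limitations

* Weights, thresholds and the criteria themselves encode stakeholder
  judgment; the package makes the arithmetic reproducible, not the
  elicitation.
* No inter-rater model: the data carry one consensus score per cell, so
  rater disagreement is only representable through the certainty levels.
* Spreadsheet workbooks are not read directly; export the value sheet to
  CSV and map headers with `score_dialect()`.
* No geographic computation: isolation is an input score, north-to-south
  order is input row order, and no maps are drawn.
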