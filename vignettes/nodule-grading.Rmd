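---
title: "Grading pulmonary nodules: the PNI-GARS and Lung-RADS rule engines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading pulmonary nodules: the PNI-GARS and Lung-RADS rule engines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnigars)
```

## The problem

Low-dose CT screening finds large numbers of pulmonary nodules, and the
clinical question for each one is whether it warrants intervention.
Structured reporting systems answer it with deterministic rules over a small
set of imaging features. This package implements two such systems as rule
engines over a common nodule record, together with the machinery to compare
them as diagnostic tests against surgical pathology:

* **Lung-RADS 2022** (ACR): categories 1, 2, 3, 4A, 4B, 4X driven almost
  entirely by nodule size and density type, with categories 1–2 a negative
  screen and 3–4 positive.
* **PNI-GARS**: grades 0, I, II, IIIa, IIIb, IIIc, IV driven by size tiers
  plus explicit upgrade rules for malignant imaging signs and downgrade
  rules for benign findings; grades 0–II are negative, III–IV positive.

The unit of analysis is a single nodule record: density type (solid SN,
part-solid PSN, ground-glass GGN), mean diameter in millimetres to one
decimal (average of the long and short axis in the lung window), the solid
component diameter for PSN, a margin descriptor, sets of malignant signs
and benign features from controlled vocabularies, endobronchial location, a
follow-up course with the longest documented stable interval in months, and
the pathology truth.

## The PNI-GARS rules

The base grade is a size tier: at most 5 mm (any density) grade I;
(5, 8] mm grade II; (8, 10] IIIa; (10, 20] IIIb; (20, 30] IIIc. A PSN whose
solid component exceeds 5 mm is grade IV outright. Tier bounds are
half-open with the upper bound inclusive: the micronodule rule is stated
"at most 5 mm", and the large-nodule tier "up to 30 mm", so 8.0 mm belongs
to II, 10.0 to IIIa, 20.0 to IIIb and 30.0 to IIIc. This is a convention
choice — the tier notation "8 ~ 10 mm" does not by itself fix which end is
closed — and is flagged here because other conventions would move nodules
sitting exactly on a bound by one sub-level.

Upgrades: the *special signs of early malignant lesions* — vacuole,
vascular convergence, a solid component appearing within a GGN, and, among
the "etc." signs, pleural indentation and the lobulation sign — climb one
sub-level per sign along II → IIIa → IIIb → IIIc → IV; two or more force
grade IV. The stronger suspicious signs (spiculation, a GGN that doubles
within a year or whose density exceeds −600 HU, enlarged lymph nodes,
shrinkage with rising density) force IV directly. Signs never upgrade
grades below II (micronodules), and no grade exceeds IV.

Downgrades: satellite lesions in the same lobe, or a combined clinical and
CT picture of inflammation, lower the grade one level with floor I —
grade 0 is reserved for the enumerated definitely benign morphologies
(pure calcification, fat, spherical atelectasis, perifissural nodules).

Stability: an SN unchanged for ≥ 2 years, a sub-solid nodule unchanged for
≥ 5 years, or any nodule that shrank or disappeared, is grade I. A PSN
stable for anything between 2 and 5 years keeps its grade — deliberately
conservative, since part-solid malignancies can be indolent over months.

**Precedence.** The source tables list the rules but not their order. The
engine applies: definitely-benign → stability → base grade → sign upgrades
→ benign downgrade → endobronchial floor. The choice is driven by
management intent: a calcified hamartoma or a five-year-stable nodule
should not be escalated by a spiculated margin, so the terminal rules fire
first; the endobronchial floor (grade III — realized as IIIb for
(10, 20] mm nodules, otherwise at least IIIa, since no sub-tier is stated)
re-applies after the benign downgrade because an endobronchial lesion
warrants bronchoscopic attention regardless of surrounding scarring. Each
classification returns a trace of the rules that fired, and replaying the
trace reproduces the grade.

Two deliberate non-rules: the grade II descriptor "partial edge smooth" is
treated as descriptive rather than a gate (the tables give no alternative
assignment for a 5–8 mm nodule with another margin), and margin tokens
influence the grade only through the sign-upgrade path, not as an
independent grade assignment.

## The Lung-RADS rules

As exercised at a single pre-surgical baseline: category 1 for complete
calcification or fat; every GGN up to 30 mm is category 2 (the cohort
domain excludes larger nodules; exactly 30.0 mm is taken as category 2,
a boundary the source material never exercises); SN cut points at 6, 8 and
15 mm for categories 2/3/4A/4B; PSN driven by total diameter (6 mm) and
then the solid component (6 and 8 mm). A category 3 or 4 nodule with an
additional suspicious finding (default trigger set: spiculation, enlarged
lymph nodes, GGN doubling within a year; configurable, as the 4X criteria
are the least codified part of the system) becomes 4X. A category 3 nodule
stable ≥ 6 months drops to 2; a 4A stable ≥ 3 months drops to 3 — one step
per documented interval, and 1/2/4B/4X never move. Growth during follow-up
is carried on the record but does not feed the baseline category.

## Diagnostic accuracy and tests

For a stratum (SN, PSN, GGN, or all) and a system, the screen labels cross
pathology truth into a TP/FN/FP/TN table; sensitivity TP/(TP+FN),
specificity TN/(FP+TN) and agreement rate (TP+TN)/n follow, each with a
Wald interval p ± 1.959964·√(p(1−p)/n) clipped to [0, 1]. The Wald choice
is itself a reconstruction: the published intervals match it at one-decimal
rendering in every spot-checked cell except a single lower bound (the PSN
Lung-RADS specificity, printed 1.2 where Wald gives 1.3), which the tests
therefore assert only to within 0.1 percentage point. The interval is
degenerate at p = 0 or 1, as Wald is.

Percentages are rendered by a two-stage rounding: the proportion is carried
to four decimals, then expressed as a one-decimal percentage, half away
from zero. The two stages matter: 2446/3018 = 0.810470… renders as 81.1
via 0.8105, where single-stage rounding would give 81.0; only the
two-stage convention reproduces all 24 published accuracy percentages
simultaneously.

Between-system comparisons use McNemar's test on discordant pairs for
sensitivity and specificity (exact two-sided binomial below 25 discordant
pairs, otherwise the uncorrected χ² — the variant used in the source
analysis is unstated, and the exact test is the safe small-sample choice)
and, for agreement rates, a 2×2 test chosen by the expected-frequency
rule: Fisher's exact probability method when n < 40 or the minimum
expected count T < 1; Yates-corrected χ² when n ≥ 40 and 1 < T < 5;
otherwise plain Pearson. "More than 40" is read as n ≥ 40 so the rule has
no gap; T exactly 1 or 5 falls to Pearson by elimination. The χ² variants
are delegated to `stats::chisq.test` (whose Yates correction clamps
|O−E|−0.5 at zero, as required) and Fisher to `stats::fisher.test` (the
two-sided probability method); the test suite cross-checks them against
independent oracles — full hypergeometric enumeration for Fisher on every
2×2 table with total ≤ 60, and expected-count summation plus the
n(ad−bc)²/(r₁r₂c₁c₂) shortcut for Pearson.

The published χ² statistics for the agreement-rate comparisons are *not*
reproduced or asserted anywhere: they require the unprinted joint
cross-classification of the two systems, and no arrangement of the printed
margins recovers them. The testing toolkit ships with property-based
coverage instead.

## Synthetic cohorts and the benchmark reconstruction

`generate_cohort()` expands a list of blocks — count × density type ×
pathology × feature template, with diameters drawn uniformly from a stated
millimetre range and rounded to one decimal, matching the measurement
convention — under a caller-supplied seed (Mersenne–Twister, recorded in
the output's `generator` attribute). It emulates the *structure* of a
surgical cohort: marginal composition, size tiers, feature steering. It
does not emulate radiological reality — no correlation between size and
sign prevalence, no patient-level clustering of multiple nodules (the
source cohort had 7,781 nodules in 6,511 patients; all statistics here are
nodule-level), no center effects, no inter-reader variability. Passing
tests on synthetic cohorts therefore validate the rule engines and the
statistics, not the systems' clinical performance.

`reconstruct_table3_cohort()` is the deterministic special case: 7,781
records (3,018 SN, 1,709 PSN, 3,054 GGN) built so that classifying them
with both engines reproduces the published per-stratum confusion tables
cell for cell. The published data fix only the per-system margins; the
joint behaviour of the two screens is chosen as the maximal-concordance
feasible arrangement per stratum, and the steering features are minimal —
size-tier choice; a single vacuole sign to make a sub-6-mm nodule
PNI-positive while Lung-RADS-negative; satellite lesions to downgrade a
PNI grade to negative while Lung-RADS stays positive. Any other feasible
joint would reproduce the same margins; none is claimed to be the real
cohort. Malignant GGNs can be annotated with the published pathology
spectrum (979 AIS, 946 MIA, 560 IAC; the three-record remainder of the
2,488 is labelled `other` since its subtype is unstated).

```{r}
cohort <- classify_cohort(reconstruct_table3_cohort())
compare_systems(cohort)$summary[, c("stratum", "system", "tp", "fn", "fp", "tn",
                                    "se_pct", "sp_pct", "ar_pct")]
```

## Worked single cases

```{r}
hamartoma <- nodule_record("case1", "SN", 11.0,
                           benign_features = c("pure_calcification", "fat"))
classify_lungrads(hamartoma)$category
classify_pnigars(hamartoma)$grade

stable_psn <- nodule_record("case2", "PSN", 9.0, solid_component_diameter = 4.0,
                            stability_months = 16, course = "unchanged")
classify_lungrads(stable_psn)$category   # 3 downgraded to 2 after 6 months
classify_pnigars(stable_psn)$grade       # IIIa: sub-solid stability needs 5 years
```

One documented divergence: a 14.9 mm solid nodule stable for ~5 months is
published as Lung-RADS 3 (4A downgraded after 3 months) with PNI-GARS IIIc,
but the size tiers alone give IIIb; IIIc requires an upgrade sign the case
description does not state. The engine reproduces the Lung-RADS category
and leaves the PNI grade at what the stated features imply.

## Numerical and degenerate-input choices

* Diameters are compared as one-decimal millimetre values; all thresholds
  are exact comparisons on that grid, so there are no floating-point ties.
* Stability thresholds convert years at 2 y = 24 months, 5 y = 60 months.
* An empty cohort or stratum is an error in tabulation (`confusion`), and
  strata absent from a cohort are skipped in `compare_systems`.
* `wald_ci` requires n > 0; sensitivity/specificity refuse tables with no
  positive/negative truth rather than returning NaN.
* McNemar with zero discordant pairs returns p = 1 and statistic 0.
* Problem sizes in the shipped tests: full 7,781-record reconstruction and
  classification end to end; Fisher oracle enumeration over all 2×2 tables
  with total ≤ 60 evaluated once per symmetry orbit (the two-sided p is
  invariant under row/column swap and transpose, which is also verified);
  1,000 random tables for the Pearson identities; 0.1 mm sweeps for
  monotonicity.

## Limitations

The engines encode only the rules the record schema can express: no
volumetry, no densitometry (GGN density thresholds enter as boolean
signs), no management recommendations, no "S" modifier, no prior-exam
logic beyond the single documented stable interval. The reconstruction
fixes margins, not the true joint distribution, so paired statistics
computed from it (McNemar discordances) reflect the chosen joint, not the
source cohort's. The confidence intervals are Wald by design and share its
known degeneracies at extreme proportions.
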