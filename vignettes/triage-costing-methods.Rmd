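---
title: "Methods: score-based triage accuracy and activity-based imaging costs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: score-based triage accuracy and activity-based imaging costs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triagecost)
```

## The pathway being modelled

`triagecost` models a two-stage chest-imaging work-up. A patient with a
doubtful finding on chest radiography (CXR) undergoes digital tomosynthesis
(DTS) on the same X-ray stand. Two radiologists independently score the
marker lesion — the largest, most conspicuous finding when several are
suspected — on a 5-point ordinal confidence scale: 1–2 definite/probable
benign, extra-pulmonary, or pseudolesion; 3 indeterminate; 4–5
probable/definite pulmonary lesion. Consensus scores of 1–2 route the
patient to a follow-up radiograph at about six months; 3–5 route to CT
within a week. The package quantifies two consequences of that rule: reader
performance against a reference-standard truth, and the hospital's annual
imaging cost relative to a CT-only work-up.

## Truth model and classification rule

The reference standard assigns each patient one of eight lesion categories.
Four — pulmonary opacity, primary lung neoplasm, ground-glass
opacity/nodule, non-calcified solid nodule — constitute the positive state
("non-calcified pulmonary lesion deserving CT"); pulmonary scars, calcified
solid nodules, pleural plaques and pseudolesions are negative. `map_truth()`
is total and deterministic over this enum.

`classify()` turns one reader's scores into confusion counts. The score-3
policy deserves emphasis: an indeterminate reading is clinically a failure
of the modality to resolve the question, so by default it counts against
the reader — a false negative on a positive patient, a false positive on a
negative one. Because indeterminate patients still go to CT, this "penalise"
convention makes specificity, not sensitivity, the statistic that registers
wasted CT examinations. The policy is exposed as an argument
(`penalise`/`exclude`/`favour`) for sensitivity analyses; only the default
is asserted against reference values.

```{r classify}
fx <- study_fixture()
pr <- confusion_to_records(fx$confusion$r1$DTS)
confusion_metrics(classify(pr$records, pr$truth))
```

Metrics are held as exact ratios and rounded (half-up, to integer percent)
only when printed. A metric whose denominator is empty is `NA`, never zero.

## Reader statistics

**ROC area.** `auc_ordinal()` computes the nonparametric (Mann–Whitney)
area: the probability that a random positive outscores a random negative,
ties credited one half. On a 2×5 score table this is a closed sum, and the
test suite checks it against an exhaustive pairwise enumeration and against
an independent ROC implementation. The standard error is Hanley–McNeil's
moment approximation with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`. The paired
comparison of two areas measured on the same patients uses
`z = (A1-A2)/sqrt(se1^2 + se2^2 - 2 r se1 se2)`. For `r` the original
method interpolates a published table indexed by the average within-class
score correlation and the average area; this package instead uses the
average of the two within-class rank correlations directly (Spearman by
default), which is the table's input axis and a close surrogate for its
output over the table's range. A user who wants the tabulated value can pass
`r` explicitly. No reference AUC comparison is asserted numerically, so only
the qualitative behaviour (sign, reduction at `r = 0`, p shrinking with n)
is tested.

**Confidence-interval method.** The default 95% interval is the normal
interval on the Hanley–McNeil SE, matching the cited error model; a
logit-scale interval is selectable for areas near 1 where the symmetric
interval spills outside (0, 1). Neither is asserted against reference
values, which do not state their interval method.

**Paired tests.** Sensitivity, specificity and predictive values between
modalities are compared with McNemar's test: the continuity-corrected
chi-square `(|b-c|-1)^2/(b+c)` on the discordant pairs, switching to the
exact binomial p value when fewer than 25 pairs are discordant — small
discordant counts are plausible at these cohort sizes and the exact test
costs nothing. Accuracy uses the Yates-corrected chi-square on the 2×2
correct/incorrect table; interpretation times use the Wilcoxon signed-rank
test with zero differences dropped (degenerate inputs return p = 1,
flagged, rather than erroring mid-pipeline).

**Agreement.** `kappa_weighted()` implements Cohen's weighted kappa on the
fixed 1–5 scale. Linear weights are the default: for a 5-point ordinal
scale they are the common convention and do not overweight extreme
disagreements the way quadratic weights do; quadratic is selectable. Bands
follow the usual cut-offs (poor < 0.20 ≤ fair < 0.40 ≤ moderate < 0.60 ≤
good < 0.80 ≤ very good), left-closed so κ = 0.40 is "moderate".

**Consensus.** Discrepant readings that would change management are merged
by `consensus_scores()`: when the two readers fall on opposite sides of the
triage boundary the higher (more suspicious) score wins — unresolved
suspicion is never dismissed on one reader's say-so; within a band, reader
1's score is kept since the choice cannot alter routing. A real
adjudicating third reader can be supplied simply by passing their scores as
the consensus column.

## Triage and utilisation

`triage()` applies the score rule deterministically and `ct_fraction()`
reports the exact proportion routed to CT. Patients whose DTS is
subdiagnostic (e.g. unable to hold the upright position) carry a DTS
examination cost with no diagnostic yield; their onward route is
configurable and defaults to CT, again because unresolved suspicion cannot
be dismissed. The ~6-month follow-up radiograph of the benign route belongs
to a later accounting period, so `tally_utilisation()` counts it only when
`count_followup_cxr = TRUE`.

## Costing model

All currency is handled as integer cents internally, because the quantities
of interest are chains of exact multiplications (an annual cost is
examination counts times unit costs) and floating-point drift would be
visible at the cent level. Division — depreciation, capacity allocation —
returns unrounded values; rounding (half-up) happens only at report
boundaries.

Unit full costs come in two modes. In *authoritative mode* the five
components (contrast, medical personnel, radiographers, nursing, asset
depreciation) are supplied directly in the configuration and `unit_cost()`
just sums them exactly. In *model mode* the capacity components can be
constructed from first principles: straight-line depreciation
(`annual_depreciation()`, price over useful life — ten years is the
conventional life for radiological equipment) and per-examination
allocation by mean occupation time over practical capacity hours
(`allocate_capacity_cost()`; 2,600 h/year for the radiography stand, 3,030
for CT, 6/13/15/19 min occupation for CXR/DTS/unenhanced CT/contrast CT in
the shipped configuration). The shipped reference configuration carries the
printed component values because the published depreciation allocations are
not exactly recoverable from the published asset table and capacity hours —
the printed annual depreciation figures themselves disagree with the stated
ten-year straight line (3,750 against 30,000/10; 155,250 is 1,242,000 over
*eight* years) — so model mode is a documented construction, not a target.

`scenario_cost()` is linear in counts and unit costs; subdiagnostic DTS
examinations are costed at the DTS unit cost. `differential_saving()` is
the before-minus-after difference and is antisymmetric by construction.
`break_even()` returns the smallest whole number of examinations whose
cumulative contribution margin (reimbursement minus variable unit cost)
covers the fixed capacity cost — an integer-ceiling in cents, so 478.47
becomes 479.

```{r costs}
uc <- fx$unit_costs
tab <- list(cxr = uc$cxr, dts = uc$dts, ct = uc$ct_unenhanced)
scenario_cost(scenario("before", fx$utilisation_before, tab, "unenhanced"))
scenario_cost(scenario("after", fx$utilisation_after, tab, "unenhanced"))
break_even(30000, 62.7)
```

## The synthetic-cohort generator

`generate_cohort()` emulates the *statistical* structure of a two-reader
reading study; it is the package's test bed, not an image simulator. Its
defaults are fixed at the reference study's conditions:

- **n = 465**, prevalence 144/465, category mix proportional to the
  reference taxonomy counts (60/5/47/32/26/23/36/236). A user-supplied
  prevalence rescales the mix within the positive and negative groups, so
  the mix/prevalence consistency invariant holds by construction.
- **Score models** `P(score | modality, truth)` calibrated to the aggregate
  operating points only — DTS sensitivity 0.80 / specificity 0.95, CXR 0.24
  / 0.10 — because the published per-score rows are not internally
  consistent enough to serve as exact distributions. Within-bin placement is
  a package choice.
- **Reader dependence** by a single copy-probability: reader 2 repeats
  reader 1's score with probability `reader_agreement` (default 0.85,
  between the reference CXR and DTS agreement levels) and otherwise redraws
  independently. This one knob maps monotonically onto kappa — 1 forces
  κ = 1, 0 gives independence — which suffices for agreement testing; it is
  *not* a latent-correlation model and cannot produce, e.g.,
  severity-dependent disagreement.
- **Interpretation times** lognormal, moment-matched to 66 ± 23 s (CXR) and
  103 ± 66 s (DTS), truncated at 1 s: positive, right-skewed, and matching
  the printed mean ± SD. Truncation at these parameters is numerically
  negligible.
- **Subdiagnostic DTS** drawn binomially at rate 7/465 as extra patients
  with no usable score.

Identical spec and seed give byte-identical cohorts. What passing tests on
these cohorts show is that the *pipeline arithmetic* is correct under known
generating conditions; they do not validate the score models against real
readers, real lesion-size effects (sizes are carried but do not drive
scores), or real inter-reader psychology.

## Numerical and testing choices

Problem sizes in the default test run are chosen to keep the full suite
under a minute on one CPU while leaving Monte-Carlo margins wide: 1,000
random tables for the AUC-oracle equivalence, 100 joint tables per
weighting for kappa, 200 independent-reader replicates for the kappa
null-expectation check, and 200 cohorts of n = 465 for parameter recovery,
where the exact binomial 95% CI must cover the generating
sensitivity/specificity in at least 93% of replicates (the exact CI's
conservatism makes ~95–97% typical, so 93% is a wide floor, not a tuned
threshold). Oracle equivalences are asserted to 1e-12 absolute; currency
assertions are exact in cents.

Degenerate inputs are flagged, not silently coerced: empty truth classes
error in `auc_ordinal()`, zero discordant pairs give p = 1 with a
`degenerate` flag, a rater without variation yields `NA` kappa, and a
non-positive contribution margin errors because the investment never breaks
even.

## Known limitations

- The costing deliberately excludes common costs (administration,
  facilities), discounting, VAT and multi-year net-present-value analysis;
  savings are single-period differentials under a support-capacity
  assumption (freed CT slots are reused, not wasted).
- Reference AUC and kappa values are not asserted numerically anywhere: the
  per-score and per-reader-pair inputs needed to recompute them are not
  self-consistent as published. Those statistics are instead validated by
  independent-oracle equivalence and property tests.
- Accuracy recomputed from the published CXR confusion counts (67/465 for
  reader 1) differs slightly from the published 15% (69/465); the package
  reports what the classification rules yield.
- The generator draws patients i.i.d.; it has no reading-order, learning,
  or case-difficulty structure.
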