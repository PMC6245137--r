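---
title: "Comorbidity networks for fast/slow complication progression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comorbidity networks for fast/slow complication progression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dianet)
```

This vignette is the package's own account of the model it implements, the
parameters that matter, the synthetic data it is validated on, and the
design decisions taken where the method left room for choice.

## The model

For one complication (kidney disease, heart failure, stroke, liver disease,
retinopathy, or myocardial infarction), the unit of analysis is a newly
diagnosed type-2-diabetes patient. Day 0 is the earliest day any inclusion
criterion holds: an ICD-9/10 code from the T2DM list (`t2dm_codes()`), an
HbA1C laboratory result at or above 6.5%, or an externally supplied
anti-diabetes medication day. Patients whose first complication diagnosis
falls on or before day 365 (including pre-index) are excluded; among the
rest, the fastest quartile of times-to-complication is labeled *fast*, the
slowest *slow*, and the middle half is excluded, giving two well-separated,
eventually-all-diagnosed groups.

Only facts from days 366–730 — the second year after index — become
features. The first year is skipped to avoid the instability of
diagnosis-time emergencies; extending further would bias the cohort toward
healthier, longer-observed patients. Each patient's history is reduced to a
*set* of typed tokens:

* `diagnosis` — ICD categories truncated to the first three characters
  before the first dot;
* `demographic` — gender, race (verbatim), and index-age quartile;
* `clinical_quartile` — each lab variable's per-patient summary mapped to a
  quartile (level 0–3) of the training distribution;
* `clinical_status` — pre-processed normal/abnormal variables.

Training patients' token sets define a heterogeneous network: every token
is a node and every unordered pair of tokens co-occurring in a patient is
an edge; both are counted once per patient per label. An element carried by
`k_fast` fast and `k_slow` slow patients has weight
`w = k_fast / (k_fast + k_slow)` — the empirical probability that a carrier
is a fast progressor — and a pooled two-proportion Z statistic comparing
its prevalence between the groups. Elements with `|z| < qnorm(0.975)` are
pruned (no multiple-testing correction is applied, deliberately matching
the method's construction; the pruning threshold is a per-element
confidence gate, not a family-wise guarantee).

A test patient is scored from the significant elements their token set
matches (nodes by membership, edges by membership of both endpoints):
candidates are ranked by `|z|`, the top `n_max = 12` kept, the single
lowest-weight element removed — this drops the one element arguing most
strongly *against* fast progression, boosting the signal of the rest — and
the surviving weights combined under an independence assumption:
`P(fast) = Π w_i / (Π w_i + Π (1 − w_i))`. This is a naive-Bayes posterior
over element carriage with a uniform class prior, which the balanced
training design justifies.

## Parameters and defaults

| parameter | default | meaning / rationale |
|---|---|---|
| feature window | (365, 730] days | second year after index |
| `q_fast`, `q_slow` | 0.25, 0.75 | nearest-rank labeling quantiles |
| `min_frac` | 0.01 | token must be carried by ≥ 1% of patients |
| `min_diag`, `median_mult` | 5, 2 | diagnosis-count patient filter |
| `alpha` | 0.05 | two-sided pruning significance |
| `n_max` | 12 | element cap in scoring; sweep grid 7–20 |
| `test_frac`, `repeats` | 0.2, 5 | holdout protocol |
| threshold | 0.5 | sensitivity/specificity operating point |
| lab summary | mean | per-patient reduction of repeated measurements |

The classification threshold deserves a caveat: the product score is
**uncalibrated**. With many matched elements whose weights sit on one side
of 0.5, probabilities pile up near 0 or 1, and a fixed 0.5 threshold can
give degenerate sensitivity/specificity even when the *ranking* (AUC) is
excellent. `roc_points()` emits the full ROC staircase so any operating
point can be chosen; AUC is the primary metric.

## What the synthetic generator does and does not emulate

`generate_cohort()` emits the three flat tables of the real schema —
diagnosis events (`STUDYID, DX_INDEX, DX_CODE`), demographics
(`STUDYID, INDEX_YEAR, INDEX_AGE, GENDER, RACE`), and a sparse wide
clinical panel (`STUDYID, AGE, DAYS_VIS_INDEX, INDEX_AGE, …`) — plus a
truth table. Each patient gets a day-0 index code, a complication diagnosis
drawn from the real ICD lists at a day uniform on (366, 730] for fast and
(1096, 1825) for slow progressors, three routine-exam events, planted
features exhibited with label-dependent probabilities, and background
features exhibited equally by both groups at 20% prevalence (the scale of
common chronic comorbidities). Planted *clinical* effects shift a lab
variable's group mean by 2 SD for exhibiting patients, so the informative
quartile arises in the measured values rather than being written directly.

Time-to-complication defaults are stand-ins with the right qualitative
shape (fast strictly earlier, fast inside two years), not calibrated to any
registry; nothing is published about those distributions beyond their
shape. Background diagnosis codes are 3-character strings (letter prefix +
two digits) chosen to be fixed points of ICD truncation and disjoint from
the index/complication lists — numbered multi-digit codes would collapse
under truncation and could collide with real code prefixes.

The generator deliberately does **not** model realistic ICD co-occurrence
structure, visit-level billing, medication records, unit-mixture artifacts,
or informative missingness. Passing tests on synthetic cohorts therefore
demonstrate that the pipeline's *mechanics* recover planted structure at
the configured effect sizes and are honest under the null — not that any
particular real-world AUC is attainable; published real-cohort numbers come
from a private registry and are not reproducible here.

Three oracles anchor the validation: `expected_node_weight()` (the analytic
mixture weight `f·p_fast / (f·p_fast + (1−f)·p_slow)`), the binomial/delta
standard errors used in recovery tests, and `planted_bayes_auc()`, the
Monte-Carlo AUC of the exact posterior under the generative model, which in
expectation upper-bounds any classifier on those features. The end-to-end
check asks the pipeline's mean holdout AUC (ten planted features 0.8/0.4,
4000 patients, five splits, 12-element cap) to come within 0.05 of that
ceiling; it loses a little because scoring uses only *present* elements
(absence of a feature carries information the product form ignores) and
because the element cap coarsens high-count patients — but gains most of it
back by selecting the strongest elements from larger matched sub-networks.

## Numerical choices and degenerate inputs

* **Quantiles** use the nearest-rank method (`sorted[ceiling(q·n)]`)
  everywhere — labeling cuts and lab quartiles — for exact, distribution-free
  semantics on small samples. Quartile assignment is `level k` iff
  `v ≤ cut_{k+1}` with ties going down; a constant training variable maps
  everything to level 0.
* **Labeling ties** resolve toward exclusion: a patient qualifying for both
  the fast (≤ cut) and slow (≥ cut) rules — possible when the two cuts
  coincide — is excluded, keeping the groups disjoint. All-identical inputs
  label everyone excluded.
* **Candidate ordering** is fully deterministic: `|z|` descending, then
  weight descending, then lexicographic token id; the removal step drops
  the first minimal-weight element in that order. Scoring is therefore
  invariant to input order.
* **Weight clamping**: in pipeline use weights are clamped to
  `[ε, 1−ε]` with `ε = 1/(n_fast + n_slow + 2)` (add-one style) so that
  co-occurring weights of exactly 0 and 1 cannot produce 0/0; the products
  are accumulated in log space.
* **Degenerate Z pools** (pooled proportion 0 or 1) return z = 0: both
  proportions are necessarily equal, so "no evidence of difference" is the
  right answer, and such elements are pruned.
* **Patients matching no significant element** receive the uninformative
  probability 0.5 with `n_used = 0`, so their fraction is reportable.
* **QC statistics** (median ± 2 SD per variable) and every other fitted
  quantity are computed on training patients only and applied unchanged to
  test patients; a dedicated test verifies that deleting any test patient
  leaves the fitted model bit-identical.

## Open design decisions

Where the method description left genuine alternatives, the package chose
and made the alternative configurable:

* **Fast definition.** Both a quantile-based ("faster than 75% of the
  population") and a window-based ("within two years") definition are
  coherent; the quantile definition is primary (`q_fast`/`q_slow`), with an
  optional hard cap (`max_fast_day`) off by default. Middle-quantile
  exclusion is the default rather than dichotomizing at a single threshold,
  since it yields the cleanly separated groups the balanced design needs.
* **Ranking significance.** "Most significant" is implemented as `|z|`
  (a signed option exists): a strongly *slow*-associated element is
  informative for the product score too, since its small weight pushes
  `p_f` up.
* **Node and edge pruning.** Significance gating is applied to both nodes
  and edges, consistent with scoring over "edges and nodes" and with
  counting significant elements of both types.
* **Per-patient set semantics.** Co-occurrence is patient-level and counted
  once regardless of event multiplicity, because weights are defined over
  patients, not visits.
* **Lab summary.** The per-patient summary is the mean of in-window values
  (configurable to last/min/max); the mean is the most noise-robust choice
  for sparse panels. Quartile boundaries are fitted on those per-patient
  summaries, so "level 3 age" means "top quartile of patients", and they are
  fitted on the training split only to avoid leakage.
* **Diagnosis-count filter.** The 5 / 2×-median patient filter counts
  in-window diagnosis *events* (configurable), with the median taken on the
  training split before any removal.

## Problem sizes

The shipped validation works at desk scale, chosen so the full suite and
the acceptance script each complete in about a minute on one CPU: planted
cohorts of 2000–4000 patients, null pruning over ~20,000 elements
(2000 patients × 200 background features), Monte-Carlo oracles at 10^5
draws, five holdout repeats. These sizes leave all statistical bands
(3 binomial/delta SEs, Mann-Whitney null SE) comfortably estimable.

## Known limitations

* No ICD-9↔ICD-10 equivalence mapping: codes are opaque prefixed strings,
  so the same condition coded in the two revisions yields two tokens.
* Scoring ignores feature *absence*; the product form is a presence-only
  naive Bayes and saturates once many similar-weight elements match.
* No score calibration and no multiple-testing correction, by design
  fidelity; both would be natural extensions.
* The between-complication correlation (`progressor_correlation()`) is the
  phi coefficient on the patients labeled in both cohorts; it is symmetric
  by construction, so direction-dependent variants of that statistic cannot
  be expressed.
* The medication inclusion arm is a per-patient day list supplied by the
  caller; proprietary medication dictionaries are not bundled, and the arm
  is inactive when absent.
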