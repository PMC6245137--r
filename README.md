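# dianet

Graph-based prediction of **fast vs. slow progression to diabetes
complications** from longitudinal electronic-health-record (EHR) tables.

## The problem

Most type-2-diabetes (T2DM) patients eventually develop one of the major
complications — kidney disease, heart failure, stroke, liver disease,
retinopathy, or myocardial infarction. For care planning, the clinically
useful question is not only *whether* but *how fast*: patients whose time
from diabetes diagnosis to first complication lies in the fastest quartile
of the population ("fast progressors") need different management than those
in the slowest quartile ("slow progressors").

`dianet` implements a comorbidity-network approach to this question:

1. **Cohort logic.** Day 0 is the first day any inclusion criterion holds
   (a T2DM ICD-9/10 code, HbA1C ≥ 6.5%, or an anti-diabetes medication
   flag). The first complication diagnosis is detected by prefix-matching
   ICD code lists. Patients whose complication occurs within one year of
   index are removed; the remainder are labeled fast (time ≤ 25th
   nearest-rank percentile) or slow (≥ 75th). Only facts from the *second
   year* after index (days 366–730) become features.
2. **Typed feature tokens.** Diagnoses truncated to 3-character ICD
   categories, demographics (gender, race, age quartile), and clinical lab
   variables reduced to per-patient quartile or normal/abnormal tokens,
   after range and median ± 2 SD quality control. Tokens present in < 1% of
   patients, and patients with < 5 or > 2× the median number of in-window
   diagnoses, are dropped; classes are balanced by downsampling.
3. **Heterogeneous network.** Every training patient contributes its tokens
   (nodes) and all unordered token pairs (edges) once. An element's weight
   is the fraction of its carriers who are fast progressors,
   `w = k_fast / (k_fast + k_slow)`, and its significance is the pooled
   two-proportion Z statistic comparing prevalence between groups. Elements
   with |z| below the two-sided 95% critical value are pruned.
4. **Risk score.** For a test patient, the significant nodes/edges matching
   their history are ranked by |z|; the top *n* ≤ 12 are kept, the single
   lowest-weight element w_h is removed, and the remaining weights are
   combined assuming independence:
   `p_t = Π w_i`, `p_f = Π (1 − w_i)`, `P(fast) = p_t / (p_t + p_f)`.
5. **Evaluation.** Repeated stratified 80/20 holdout; rank-based AUC with
   tie credit, sensitivity and specificity; an element-cap sweep over
   n ∈ {7, 10, 12, 15, 17, 20}; and the between-complication correlation of
   fast-progressor status (phi coefficient).

Because real T2DM registries are private, the package ships a
**synthetic-EHR generator** that emits the same three flat tables
(diagnosis events, demographics, wide clinical panel) with *planted*
feature effects — each planted feature is carried by fast progressors with
probability `p_fast` and slow ones with `p_slow` — plus analytic and
Monte-Carlo oracles (`expected_node_weight()`, `planted_bayes_auc()`) that
say exactly what the pipeline should recover.

## Worked example

```r
library(dianet)

cfg <- synth_config(n_patients = 2000, complication = "kidney", seed = 42)
cohort <- generate_cohort(cfg)   # patients / diagnoses / labs / truth tables

res <- run_experiment(cohort, "kidney", n_grid = c(7, 12, 20),
                      repeats = 3, seed = 1)
res
#> <experiment_result> 3 splits (seeds 2, 3, 4)
#>   complication n_max   auc auc_sd sensitivity sensitivity_sd specificity
#> 1       kidney     7 0.916 0.0169           1              0           0
#> 2       kidney    12 0.956 0.0164           1              0           0
#> 3       kidney    20 0.967 0.0137           1              0           0
```

The mean test AUC of ~0.95 at the 12-element cap approaches the Bayes
ceiling of the generative model (`planted_bayes_auc(cfg)` ≈ 0.97): the
network recovers nearly all of the planted signal. (The default planted
effects are strong; sensitivity/specificity at the fixed 0.5 threshold are
degenerate here because the uncalibrated product score pushes almost all
probabilities toward 1 — see the vignette.)

Fitting on the full labeled cohort and inspecting the top conditions:

```r
prep   <- prepare_cohort(cohort, "kidney")
labels <- setNames(prep$labels$label, prep$labels$study_id)
ids    <- names(labels)[labels %in% c("fast", "slow")]
model  <- fit_progression_model(prep, ids, seed = 1)
top_conditions(model$network, m = 3)$by_z
#>            element k_fast k_slow    weight        z
#> 419 diagnosis|P02|    408    192 0.6800000 13.88079
#> 736 diagnosis|P09|    403    195 0.6739130 13.35616
#> 369 diagnosis|P01|    412    208 0.6645161 13.22634
```

The planted features (codes `P01`…`P10`, exhibited by 80% of fast and 40%
of slow progressors) top the ranking, with weights near the analytic value
`expected_node_weight(0.8, 0.4, 0.5) = 2/3`.

A YAML-driven command-line interface wraps the same stages
(`simulate | label | network | score | evaluate | all`):

```sh
Rscript inst/cli/dianet.R --config inst/extdata/demo-config.yaml --out artifacts/
```

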