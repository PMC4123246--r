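# smvdiscover

Quality-aware discovery and blinded validation of case/control serum
protein biomarkers from affinity-proteomic (RFU) matrices.

## The problem

Blood-based biomarker studies fail to validate with depressing regularity,
and a major culprit is *preanalytic variability*: clotting time,
centrifugation, handling and storage shift the measured levels of many
serum proteins in a coordinated way. When collection practice differs
between study sites — or worse, between cases and controls at the same
site — these shifts masquerade as disease biomarkers. A cytoplasmic
protein released by cell lysis can look like a superb cancer marker in
training and evaporate in the first independent cohort.

`smvdiscover` implements a discovery workflow built around that failure
mode, for analysts working with multiplexed affinity proteomics
(SOMAscan-style relative fluorescence unit matrices, ~10²–10³ analytes):

1. **SMV quality scoring** — Sample Mapping Vectors are small protein
   panels typifying contamination modes (30 cell-lysis proteins, 4
   complement-activation proteins, 16 platelet proteins; only the first
   two apply to serum). Each sample gets a robust-z panel score
   `z = (log2 RFU − ref median) / (1.4826 · ref MAD)`, aggregated as the
   median over panel proteins; the composite is the max over panels.
2. **Quality-stratified selection** — candidate markers are found by
   two-sample Kolmogorov–Smirnov tests on the uniformly well-collected
   stratum (empirical cutoffs give an 80/20 high/low split), with
   Benjamini–Hochberg control and a top-15 cap.
3. **Robustness filtering** — a candidate is kept only if it is
   uncorrelated with every SMV score (|Spearman ρ| < 0.3 in controls),
   retains ≥ 60 % of its above-chance AUC in the low-quality stratum, and
   its control-group median varies ≤ 1.5-fold across collection sites.
4. **Backward-elimination random forest** — a bagged decision-tree
   classifier is trained on the survivors; the least gini-important
   marker is removed iteratively down to one, and the final panel is the
   smallest whose out-of-bag AUC is within 0.01 of the best. Calls use a
   fixed case threshold of 0.45 on the vote fraction.
5. **Blinded validation and reporting** — predictions are a pure function
   of the barcode-keyed RFU matrix (the label ledger is only readable
   after predictions are persisted), scored as ROC/AUC by histology,
   stratified sensitivity/specificity with Wilson 95 % CIs, and
   prevalence-adjusted PPV/NPV via Bayes' rule.

A first-class synthetic cohort generator plants all of the above
structure — graded disease effects by histology (AD/SQ) and stage, decoy
markers that respond to contamination, per-site contamination scales and
site-level case/control collection bias — so every claim the package makes
about confounding is testable against known truth.

## Worked example

Simulate a confounded 4-site training study (363 samples, 120 analytes, 7
true markers, 3 HSP90-like decoys, collection bias at two sites), run the
full discovery pipeline, and validate on an unconfounded cohort:

```r
library(smvdiscover)

menu   <- generate_analyte_menu(120, n_true = 7, n_confounded = 3, seed = 42)
design <- default_training_design(seed = 42, confounded = TRUE)
cohort <- simulate_cohort(menu, design)

res <- discover_classifier(cohort$matrix, cohort$annotations,
                           menu_smv_panels(menu),
                           run_options(n_trees = 500, seed = 42))
res$candidates[, c("analyte_id", "ks_d", "max_abs_smv_correlation",
                   "passes_robustness")]
```

```
   analyte_id ks_d max_abs_smv_correlation passes_robustness
1    SERPINA3 0.47                   0.066              TRUE
2        MMP7 0.46                   0.049             FALSE
3         CA6 0.45                   0.020              TRUE
...
8     HSP90.1 0.35                   0.578             FALSE
9     CELL.03 0.34                   0.471             FALSE
10    HSP90.3 0.32                   0.656             FALSE
```

The 7 planted true markers top the KS ranking; the confounded decoys
(`HSP90.*`) and raw contamination-panel proteins also reach the candidate
list — on this biased cohort they genuinely separate cases from controls —
but their SMV correlations (0.47–0.76) betray them and the robustness
filter removes every one. Elimination then shrinks the survivors to a
compact panel:

```r
res$classifier$marker_panel          # "SERPINA3" "CA6" "CRP" "MMP12" "CNDP1"
res$classifier$forest$oob_auc        # 0.969

va   <- simulate_cohort(menu, default_training_design(seed = 99))
vm   <- median_normalize(va$matrix,
                         exclude = unlist(menu_smv_panels(menu)$panels))$matrix
perf <- stratified_performance(predict(res$classifier, vm), va$annotations)
perf$auc
```

```
  histology   auc
1       all 0.912
2        AD 0.876
3        SQ 0.988
```

The frozen classifier transfers to the blinded cohort, squamous histology
is detected better than adenocarcinoma, and the stratified table shows
sensitivity rising with stage (stage I AD 52 %, stage II–IV AD 92 %) —
the qualitative signatures the workflow is designed to preserve.

A command-line front end with subcommands `simulate`, `preprocess`, `qc`,
`select`, `train`, `predict`, `evaluate` and `run-all` ships at
`inst/cli/smvdiscover.R` (exit codes: 0 success, 2 validation error,
3 blinding violation).

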