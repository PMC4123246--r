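---
title: "Quality-aware serum biomarker discovery: models, defaults and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality-aware serum biomarker discovery: models, defaults and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the statistical model behind each stage, the tunable parameters and why
their defaults are what they are, what the synthetic cohort generator does
and does not emulate, and the places where the design was genuinely open
and a choice had to be made.

## The workflow and its assumptions

The pipeline addresses a specific failure mode of blood-based biomarker
studies: protein-level shifts caused by blood collection and processing
(cell lysis, complement activation, platelet activation) that differ
between study sites or between cases and controls, and therefore
masquerade as disease biomarkers. Its stages are:

1. per-sample median normalization and (optionally) calibrator-based
   per-analyte plate scaling of the positive RFU matrix;
2. Sample Mapping Vector (SMV) scoring of each sample's collection
   quality, and classification into a high/low quality stratum;
3. two-sample Kolmogorov–Smirnov candidate selection within the
   high-quality stratum, under Benjamini–Hochberg control;
4. a three-part robustness filter (SMV correlation, low-stratum
   retention, cross-site consistency);
5. gini-importance backward elimination of a bagged decision-tree
   classifier, selected to the smallest panel within an OOB-AUC
   tolerance, frozen with a fixed 0.45 case threshold;
6. blinded prediction (a pure function of the barcode-keyed RFU matrix)
   followed by unblinded stratified evaluation and prevalence-adjusted
   predictive values.

The core modelling assumptions: RFU noise is multiplicative (hence all
statistics operate on log2 values); contamination acts as a per-sample
latent severity that moves whole protein panels coherently; and a genuine
disease marker's discrimination should not depend on the contamination
stratum a sample happens to fall in.

## SMV scoring

Panel analytes are standardized to robust z-scores against a reference
cohort, `z = (log2 RFU − ref median) / (1.4826 · ref MAD)`, and a sample's
panel score is the **median** of its panel z-scores. The median (rather
than a mean or a norm) makes the score monotone in a common shift of the
panel while ignoring individual assay failures. The composite score is
the **max** over applicable panels: a sample is compromised if *any*
contamination mode is elevated. For serum, the platelet panel is carried
but never scored, since platelets are consumed during clotting and their
release signature is uninformative in that matrix.

Two cutoff modes exist. Fixed cutoffs (default 2 robust-z per panel)
express an absolute notion of "visibly contaminated". The pipeline
default is instead `empirical:0.8`: a common cutoff placed at the
0.8-quantile of the composite score over the training cohort, with
boundary ties resolved toward high quality. This reproduces the 80/20
quality split used in practice — the field derives its cutoffs
empirically from the cohort at hand — and guarantees the low stratum is
populated, which the robustness filter requires.

## Candidate selection and the robustness filter

KS tests are run per analyte (case vs control, log2 scale) in the
high-quality stratum only, requiring at least 10 samples per class. BH
control at `fdr_q = 0.05` plus a `max_candidates = 15` cap keeps the
candidate list the size a validation assay can absorb; survivors are
ranked by descending D with ties broken by smaller p, then analyte id.

A candidate must then pass all three of:

* **(a) SMV correlation** `< r_max = 0.3`, computed over *control samples
  only*. This restriction matters: when collection quality is itself
  confounded with case status, disease markers correlate with SMV scores
  through the case mix, and a pooled correlation would indict genuine
  biology. Controls isolate the preanalytic response.
* **(b) low-stratum retention**: oriented by the candidate's direction,
  `auc_low − 0.5 ≥ retain_frac · (auc_high − 0.5)` with
  `retain_frac = 0.6`. A real marker performs comparably in sloppier
  samples; a quality artefact does not. Note the low stratum is small by
  construction (20 % of the cohort), so this criterion carries sampling
  noise of roughly ±0.06 AUC — strict thresholds here trade a few true
  markers for protection against decoys.
* **(c) site consistency**: maximum pairwise fold change of control-group
  medians across sites `≤ fold_max = 1.5` (sites with fewer than 5
  controls are excluded). Contamination-responsive proteins show
  multi-fold site shifts; clean markers sit near 1.

All three diagnostics are recorded on every candidate whether it passes
or not, so the filter's reasoning is auditable.

## Classifier and panel-size rule

The classifier is a bagged decision-tree ensemble (1000 trees, `sqrt`
features per split, minimum leaf 5 — unpublished in the source studies,
chosen for stable OOB estimates at n ≈ 400 and exposed in
`forest_config()`). Elimination removes the least gini-important marker
per round (ties: smaller KS D, then analyte id), with per-size sub-seeds
derived from the run seed so the trace is bit-for-bit reproducible. OOB
AUC (not error rate) is the elimination score, since AUC is the quantity
reported throughout this literature. The final panel is the smallest size
whose OOB AUC is within `tolerance = 0.01` of the maximum over all sizes —
an operationalization of "best balance between highest AUC and fewest
markers".

Two numerical caveats discovered while testing, both documented because
they are properties of the method rather than bugs:

* a one-feature forest has perfectly correlated trees; adding even a pure
  noise feature decorrelates them and can raise OOB AUC by 0.01–0.04, so
  the parsimony rule does not reliably discard a dominated companion in
  two-marker problems (it always ranks it least important and removes it
  first);
* conversely, once the joint OOB AUC exceeds roughly 0.93, the marginal
  AUC of one more true marker falls below the 0.01 tolerance, so the rule
  deliberately trims genuine markers from large planted panels. Parsimony
  and complete recovery are in tension by design.

The 0.45 case threshold is carried as a fixed constant of the method.

## The synthetic cohort generator

`generate_analyte_menu()` + `simulate_cohort()` define the study
conditions every end-to-end test runs under. The generative model for
sample *s*, analyte *a* on the log2 scale:

```
base_a + N(0, bio_sd_a) + expressed_{s,a} · stage_factor_s · log2(fold_{hist(s),a})
       + lysis_loading_a · latent_s + N(0, assay_sd)
```

* **Cohort structure**: 363 subjects over 4 sites — 94 cases (64 AD with
  stages I–IV 27/7/19/11, 30 SQ 11/5/12/2) and 269 controls (122 benign
  nodule, 147 smokers) — the size and composition of a realistic
  multi-centre serum discovery study.
* **Disease effects**: default AD fold 2.0, SQ fold 2.0^1.5 ≈ 2.8 (SQ
  effects exceed AD for every marker), multiplied by stage factors 1,
  1.25, 1.5, 1.75 — magnitudes only qualitatively anchored in the
  literature (monotone disease burden), so they are simulator defaults
  chosen to put the 7-marker study in the AUC ≈ 0.9 regime rather than at
  saturation.
* **Tumour heterogeneity**: each case expresses each true marker with
  probability 0.5 (`expression_prob`). Not every tumour sheds every
  marker; this is what makes a *panel* worth more than its best member.
* **Contamination**: latent severity per sample is log-normal with
  per-site scale (defaults 0.35–1.05 lognormal-sdlog 0.6), and the
  confounded design adds +1.5 to cases at two of four sites — the
  site-level case/control collection bias that creates convincing decoys.
  Decoys default to a genuine 1.25/1.4 disease fold *plus* lysis loading
  0.9: the dangerous, HSP90-like case of a real marker that is also a
  contamination reporter.
* **Assay noise**: log-normal at CV 5 %, the inter-assay regime of modern
  aptamer platforms.

What the generator does **not** emulate: separate covariates for clotting
time, spin force or temperature (one latent severity per sample
suffices); plate/run batch structure in the default cohorts (the
calibration op is exercised on constructed fixtures); non-Gaussian
biological tails; correlated biology between markers; missing values
(real RFU matrices are complete). Passing tests therefore demonstrate the
*logic* of quality-aware discovery under its stated model, not
performance on any real cohort.

One reduced-menu artefact deserves note: the test menu has 120 analytes
of which 50 belong to SMV panels, so a plain per-sample median is itself
contaminated and would leak contamination into clean analytes through the
normalization factor. The pipeline therefore computes the per-sample
median over non-panel analytes (all analytes are still scaled). At the
realistic 1033-analyte menu (50/1033 panel proteins) the two choices are
practically indistinguishable.

## Evaluation conventions

AUC is the Mann–Whitney rank statistic with ties counted ½ (identical to
the trapezoidal ROC area; the tests verify the equivalence on 1000 random
instances). Confidence intervals are Wilson score by default —
reproducing the whole-percent intervals conventionally printed for
diagnostic studies, e.g. 108/122 → 89 % (82–93) — with Clopper–Pearson as
the config-switchable alternative. Percentages are rounded half-up.
PPV/NPV use Bayes' rule from sensitivity, specificity and an assumed
prevalence (defaults 15 % and 7.5 %, the regimes relevant to CT-detected
pulmonary nodules); at the degenerate everything-benign operating point
the NPV is `1 − prevalence`.

## Blinding

Prediction consumes only the RFU matrix and emits barcode, probability
and call; the evaluation stage refuses to open the label ledger unless a
predictions file is already persisted (error class `smv_blinding_error`,
CLI exit code 3). This mechanically enforces the predictions-first
ordering that blinded validation studies commit to.

## Problem sizes used by the test suite

The simulation-backed tests run the full pipeline on the 120-analyte
menu, 363-sample default cohort at 500 trees: 20 replicate seeds for the
confounding-rescue, recovery and frozen-model properties, 6–8 seeds for
module-level properties, and 1000-instance oracle sweeps for the KS and
AUC equivalences. The acceptance script replays 6 seeds of the same
replica. These sizes were chosen so the whole suite completes in a few
minutes on a single core while keeping Monte-Carlo noise on rate
estimates near ±0.1.

## Known limitations

* The SMV aggregation (median-of-robust-z, max composite) is this
  package's formulation; the field's production formulas are unpublished,
  and only the 80/20 split and the panel sizes are externally anchored.
* The robustness thresholds 0.3 / 0.6 / 1.5 are defaults, not estimated
  quantities; criterion (b) in particular is noisy on a 20 % stratum and
  will occasionally reject genuine markers.
* The panel-size rule's 0.01 tolerance means recovered panels are
  typically 4–7 markers even when 7 are planted; treat the recovered
  panel as sufficient, not exhaustive.
* Histology-specific training (separate AD and SQ classifiers) is out of
  scope, as is probability calibration of the vote fractions.
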