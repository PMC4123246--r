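# End-to-end orchestration: normalize -> SMV QC -> quality-stratified
# discovery -> robustness filter -> backward elimination -> blinded
# prediction -> unblinded evaluation. Stage intermediates are persisted as
# csv so every step is independently auditable, and the blinded prediction
# stage never touches sample labels.

#' Pipeline run options
#'
#' Collects every tunable of the discovery pipeline with its default.
#'
#' @param quality_cutoffs per-panel robust-z cutoffs, a single number, or
#'   `"empirical:q"` (default `"empirical:0.8"`: the 80/20 quality split).
#' @param fdr_q,max_candidates candidate selection thresholds.
#' @param r_max,retain_frac,fold_max robustness thresholds
#'   (see [robustness_filter()]).
#' @param n_trees,features_per_split,min_leaf forest hyperparameters.
#' @param tolerance panel-size selection tolerance on OOB AUC.
#' @param threshold case-probability decision threshold (default 0.45).
#' @param prevalences prevalences for predictive-value reporting.
#' @param smv_filtering logical; `FALSE` disables both quality
#'   stratification and the robustness filter (ablation mode, for
#'   demonstrating what preanalytic confounding does to a naive analysis).
#' @param seed global seed; stage seeds are derived via [substream_seed()].
#' @return List of class `run_options`.
#' @export
run_options <- function(quality_cutoffs = "empirical:0.8",
                        fdr_q = 0.05, max_candidates = 15L,
                        r_max = 0.3, retain_frac = 0.6, fold_max = 1.5,
                        n_trees = 1000L, features_per_split = "sqrt",
                        min_leaf = 5L, tolerance = 0.01, threshold = 0.45,
                        prevalences = c(0.15, 0.075),
                        smv_filtering = TRUE, seed = 1L) {
  structure(list(quality_cutoffs = quality_cutoffs, fdr_q = fdr_q,
                 max_candidates = max_candidates, r_max = r_max,
                 retain_frac = retain_frac, fold_max = fold_max,
                 n_trees = n_trees, features_per_split = features_per_split,
                 min_leaf = min_leaf, tolerance = tolerance,
                 threshold = threshold, prevalences = prevalences,
                 smv_filtering = smv_filtering, seed = as.integer(seed)),
            class = "run_options")
}

#' Discover a robust marker panel and train the classifier (in memory)
#'
#' The computational core of [run_discovery()]: median normalization, SMV
#' scoring and quality classification, KS candidate selection in the
#' high-quality stratum, robustness filtering, and gini-importance backward
#' elimination on the surviving candidates. With `opts$smv_filtering =
#' FALSE`, discovery runs on all samples and the robustness filter is
#' skipped (every candidate is carried into elimination).
#'
#' @param matrix raw RFU matrix.
#' @param annotations sample annotations.
#' @param panels an `smv_panel_set`.
#' @param opts a [run_options()].
#' @return List: `normalization`, `quality`, `candidates` (with robustness
#'   diagnostics), `classifier` (`NULL` when no candidate survives).
#' @export
discover_classifier <- function(matrix, annotations, panels, opts = run_options()) {
  norm <- median_normalize(matrix, exclude = unlist(panels$panels, use.names = FALSE))
  quality <- classify_quality(compute_smv_scores(norm$matrix, panels),
                              opts$quality_cutoffs)
  candidates <- select_candidates(norm$matrix, annotations,
                                  quality = if (opts$smv_filtering) quality else NULL,
                                  fdr_q = opts$fdr_q,
                                  max_candidates = opts$max_candidates)
  if (opts$smv_filtering && nrow(candidates) > 0) {
    candidates <- robustness_filter(candidates, norm$matrix, annotations, quality,
                                    r_max = opts$r_max,
                                    retain_frac = opts$retain_frac,
                                    fold_max = opts$fold_max)
    surviving <- candidates[candidates$passes_robustness, , drop = FALSE]
  } else {
    surviving <- candidates
  }

  classifier <- NULL
  if (nrow(surviving) >= 2L) {
    cfg <- forest_config(n_trees = opts$n_trees,
                         features_per_split = opts$features_per_split,
                         min_leaf = opts$min_leaf,
                         seed = substream_seed(opts$seed, "train"))
    grp <- annotations$group[match(rownames(norm$matrix), annotations$barcode)]
    classifier <- backward_eliminate(norm$matrix, grp, surviving, cfg,
                                     tolerance = opts$tolerance,
                                     threshold = opts$threshold)
  } else if (nrow(surviving) == 1L) {
    cfg <- forest_config(n_trees = opts$n_trees,
                         features_per_split = opts$features_per_split,
                         min_leaf = opts$min_leaf,
                         seed = substream_seed(opts$seed, "train"))
    grp <- annotations$group[match(rownames(norm$matrix), annotations$barcode)]
    f <- train_forest(log2(norm$matrix[, surviving$analyte_id, drop = FALSE]), grp, cfg)
    classifier <- structure(list(marker_panel = surviving$analyte_id,
                                 forest = f, threshold = opts$threshold,
                                 elimination_trace = data.frame(
                                   size = 1L, oob_auc = f$oob_auc,
                                   marker_removed = NA_character_,
                                   panel = surviving$analyte_id),
                                 config = cfg, tolerance = opts$tolerance,
                                 candidates = surviving),
                            class = "marker_classifier")
  }
  list(normalization = norm, quality = quality, candidates = candidates,
       classifier = classifier)
}

read_rfu_file <- function(path) {
  rfu <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  if (names(rfu)[1] != "barcode") stop_validation("%s: first column must be 'barcode'", path)
  m <- as.matrix(rfu[, -1, drop = FALSE]); storage.mode(m) <- "double"
  rownames(m) <- as.character(rfu$barcode)
  validate_rfu(m)
  m
}

#' Run the discovery pipeline against cohort files
#'
#' Reads the `<stem>_rfu.csv` / `<stem>_meta.csv` cohort, optionally
#' calibrates plates (wells flagged by an `is_calibrator` metadata column
#' are used for calibration and then dropped), runs
#' [discover_classifier()], and persists every intermediate under
#' `out_dir`: `qc_report.csv`, `candidates.csv`, `elimination_trace.csv`,
#' a `model/` archive, and `manifest.json` recording the package version,
#' seeds and thresholds.
#'
#' @param stem cohort file stem.
#' @param panels an `smv_panel_set`, or a panel csv path.
#' @param out_dir output directory.
#' @param opts a [run_options()].
#' @return The [discover_classifier()] result, invisibly, with
#'   `$out_dir` attached.
#' @export
run_discovery <- function(stem, panels, out_dir, opts = run_options()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(panels)) panels <- read_smv_panels(panels)
  cohort <- read_cohort(stem)
  matrix <- cohort$matrix; ann <- cohort$annotations
  stages <- c("read")

  if (!is.null(ann$is_calibrator) && any(ann$is_calibrator)) {
    cal_bc <- ann$barcode[as.logical(ann$is_calibrator)]
    plates <- if (!is.null(ann$plate)) stats::setNames(ann$plate, ann$barcode) else NULL
    cal <- plate_calibrate(matrix, cal_bc, plates = plates)
    keep <- setdiff(rownames(matrix), cal_bc)
    matrix <- cal$matrix[keep, , drop = FALSE]
    ann <- ann[match(keep, ann$barcode), , drop = FALSE]
    stages <- c(stages, "calibrate")
  }

  res <- discover_classifier(matrix, ann, panels, opts)
  stages <- c(stages, "normalize", "qc", "select",
              if (opts$smv_filtering) "robustness_filter", "train")

  write.csv(res$quality$scores, file.path(out_dir, "qc_report.csv"), row.names = FALSE)
  write_candidates(res$candidates, file.path(out_dir, "candidates.csv"))
  if (!is.null(res$classifier)) {
    write.csv(res$classifier$elimination_trace,
              file.path(out_dir, "elimination_trace.csv"), row.names = FALSE)
    save_classifier(res$classifier, file.path(out_dir, "model"))
  }
  manifest <- list(
    package = "smvdiscover",
    version = as.character(utils::packageVersion("smvdiscover")),
    stages = stages,
    seed = opts$seed,
    options = unclass(opts)[c("quality_cutoffs", "fdr_q", "max_candidates",
                              "r_max", "retain_frac", "fold_max", "n_trees",
                              "min_leaf", "tolerance", "threshold",
                              "smv_filtering")],
    n_candidates = nrow(res$candidates),
    panel = if (is.null(res$classifier)) character(0) else res$classifier$marker_panel,
    model_trained = !is.null(res$classifier))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$out_dir <- out_dir
  invisible(res)
}

#' Make blinded predictions and (optionally) unblind and evaluate
#'
#' The prediction stage reads only the RFU file, normalizes it, bridges
#' assay formats if requested, applies the frozen classifier and persists
#' `predictions.csv` (barcode, probability, call — no clinical fields).
#' Only after predictions are on disk is the blinding ledger (the metadata
#' file holding true labels) opened for evaluation; withholding the ledger
#' leaves the run in blinded state with predictions persisted and an
#' explicit status.
#'
#' @param classifier a `marker_classifier` or a model archive directory.
#' @param rfu_path path to the validation `_rfu.csv` file.
#' @param out_dir output directory.
#' @param ledger_path optional path to the metadata csv with true labels.
#' @param bridge optional `list(paired_old =, paired_new =)` of RFU
#'   matrices for format bridging (see [bridge_formats()]).
#' @param prevalences prevalences for predictive values.
#' @return List: `predictions`, `performance` (`NULL` while blinded),
#'   `status` (`"blinded"` or `"evaluated"`).
#' @export
run_validation <- function(classifier, rfu_path, out_dir, ledger_path = NULL,
                           bridge = NULL, prevalences = c(0.15, 0.075)) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(classifier)) classifier <- load_classifier(classifier)
  m <- read_rfu_file(rfu_path)
  m <- median_normalize(m)$matrix
  if (!is.null(bridge))
    m <- bridge_formats(bridge$paired_old, bridge$paired_new, m)
  predictions <- predict(classifier, m)
  pred_path <- file.path(out_dir, "predictions.csv")
  write.csv(predictions, pred_path, row.names = FALSE)

  if (is.null(ledger_path))
    return(list(predictions = predictions, performance = NULL, status = "blinded"))
  perf <- unblind_evaluate(pred_path, ledger_path, out_dir, prevalences)
  list(predictions = predictions, performance = perf, status = "evaluated")
}

#' Unblind persisted predictions and score them
#'
#' Evaluation is only permitted once predictions are persisted: attempting
#' to open the ledger before `predictions_path` exists is a blinding
#' violation and errors with class `smv_blinding_error`.
#'
#' @param predictions_path csv written by the prediction stage.
#' @param ledger_path metadata csv holding the true labels.
#' @param out_dir directory for the performance report.
#' @param prevalences prevalences for predictive values.
#' @return A `stratified_performance`.
#' @export
unblind_evaluate <- function(predictions_path, ledger_path, out_dir,
                             prevalences = c(0.15, 0.075)) {
  if (!file.exists(predictions_path))
    stop_blinding("blinding violation: ledger requested before predictions were persisted (%s missing)",
                  predictions_path)
  predictions <- read.csv(predictions_path, stringsAsFactors = FALSE)
  predictions$barcode <- as.character(predictions$barcode)
  ledger <- read.csv(ledger_path, stringsAsFactors = FALSE)
  ledger$barcode <- as.character(ledger$barcode)
  perf <- stratified_performance(predictions, ledger, prevalences = prevalences)
  write_performance_report(perf, out_dir)
  perf
}
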