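# Bagged decision-tree (random forest) case/control classifier with
# gini-importance backward elimination and a fixed decision threshold.
# The ensemble itself is fit with the randomForest package; this module owns
# the configuration, out-of-bag bookkeeping, the elimination schedule and
# the frozen-classifier contract.

#' Forest configuration
#'
#' @param n_trees number of trees (>= 100, so out-of-bag estimates are
#'   stable; default 1000).
#' @param features_per_split `"sqrt"` or an integer mtry.
#' @param min_leaf minimum terminal node size (default 5).
#' @param seed integer seed; all fits under this config are deterministic.
#' @return List of class `forest_config`.
#' @export
forest_config <- function(n_trees = 1000L, features_per_split = "sqrt",
                          min_leaf = 5L, seed = 1L) {
  if (n_trees < 100L) stop_validation("n_trees must be >= 100 for OOB estimation")
  if (min_leaf < 1L) stop_validation("min_leaf must be >= 1")
  if (!identical(features_per_split, "sqrt") &&
      (!is.numeric(features_per_split) || features_per_split < 1))
    stop_validation("features_per_split must be \"sqrt\" or a positive integer")
  structure(list(n_trees = as.integer(n_trees),
                 features_per_split = features_per_split,
                 min_leaf = as.integer(min_leaf),
                 seed = as.integer(seed)),
            class = "forest_config")
}

#' Gini impurity of a binary label vector
#'
#' `1 - sum(p_k^2)`; 0.5 for a balanced binary node, 0 for a pure node.
#' @param labels vector of class labels.
#' @return Gini impurity in `[0, 0.5]` for two classes.
#' @export
gini_impurity <- function(labels) {
  p <- table(labels) / length(labels)
  1 - sum(p^2)
}

#' Impurity decrease of a binary split
#'
#' The sample-fraction-weighted gini decrease
#' `gini(parent) - nL/n * gini(left) - nR/n * gini(right)`, the quantity a
#' tree accumulates into a feature's gini importance at each split.
#' @param labels parent node labels.
#' @param left logical index of the left child.
#' @return Non-negative impurity decrease.
#' @export
#' @examples
#' gini_split_decrease(c("case", "case", "control", "control"),
#'                     c(TRUE, TRUE, FALSE, FALSE))  # 0.5
gini_split_decrease <- function(labels, left) {
  stopifnot(length(labels) == length(left), is.logical(left))
  n <- length(labels)
  gini_impurity(labels) -
    sum(left) / n * gini_impurity(labels[left]) -
    sum(!left) / n * gini_impurity(labels[!left])
}

as_class_factor <- function(labels) {
  y <- factor(labels, levels = c("control", "case"))
  if (any(is.na(y))) stop_validation("labels must be 'case' or 'control'")
  if (nlevels(droplevels(y)) < 2L) stop_validation("both classes must be present")
  y
}

#' Train a bagged decision-tree ensemble
#'
#' Fits a random forest on the marker-restricted log2 matrix with bootstrap
#' aggregation. Per-sample out-of-bag (OOB) case probabilities are the
#' fraction of case votes among the trees whose bootstrap excluded that
#' sample; per-marker importance is the mean over trees of the total gini
#' impurity decrease attributed to splits on the marker.
#'
#' @param x numeric matrix or data.frame, samples x markers (log2 scale).
#' @param labels `"case"`/`"control"` per sample.
#' @param config a [forest_config()].
#' @return List of class `smv_forest`: `rf` (the fitted ensemble),
#'   `oob_prob`, `importance`, `oob_auc`, `markers`, `inbag`.
#' @export
train_forest <- function(x, labels, config = forest_config()) {
  x <- as.data.frame(x)
  y <- as_class_factor(labels)
  mtry <- if (identical(config$features_per_split, "sqrt"))
    max(1L, floor(sqrt(ncol(x)))) else min(ncol(x), as.integer(config$features_per_split))
  set.seed(config$seed)
  rf <- randomForest::randomForest(
    x = x, y = y, ntree = config$n_trees, mtry = mtry,
    nodesize = config$min_leaf, keep.inbag = TRUE, keep.forest = TRUE)
  oob <- rf$votes[, "case"]
  structure(list(rf = rf,
                 oob_prob = stats::setNames(as.numeric(oob), rownames(x)),
                 importance = rf$importance[, "MeanDecreaseGini"],
                 oob_auc = roc_auc(oob[y == "case"], oob[y == "control"]),
                 markers = colnames(x),
                 labels = y,
                 inbag = rf$inbag,
                 config = config),
            class = "smv_forest")
}

#' Backward-eliminate markers by gini importance
#'
#' Starting from the full candidate set, repeatedly fits a forest, records
#' its OOB AUC and importances, and removes the least important marker,
#' until one marker remains (ties in least importance are broken by the
#' smaller KS D, then by analyte id). The final panel is the smallest size
#' whose OOB AUC is within `tolerance` of the best OOB AUC over all sizes —
#' the operational reading of "the best balance between the highest AUC and
#' the lowest number of markers". Per-size fits use sub-seeds derived
#' deterministically from `config$seed`, so the trace is reproducible
#' bit-for-bit and the chosen model can be re-fit identically.
#'
#' @param matrix normalized RFU matrix (the marker columns are log2
#'   transformed internally).
#' @param labels `"case"`/`"control"` per sample, aligned to matrix rows.
#' @param candidates `marker_candidates` (uses `analyte_id` and `ks_d`).
#' @param config a [forest_config()].
#' @param tolerance non-negative AUC tolerance for panel-size selection
#'   (default 0.01).
#' @param threshold case-probability decision threshold recorded in the
#'   classifier (default 0.45).
#' @return List of class `marker_classifier`: `marker_panel`, `forest`
#'   (an `smv_forest` re-fit on the final panel), `threshold`,
#'   `elimination_trace` (data.frame: size, oob_auc, marker_removed,
#'   panel), `config`, `tolerance`.
#' @export
backward_eliminate <- function(matrix, labels, candidates, config = forest_config(),
                               tolerance = 0.01, threshold = 0.45) {
  if (tolerance < 0) stop_validation("tolerance must be non-negative")
  if (threshold <= 0 || threshold >= 1) stop_validation("threshold must be in (0, 1)")
  if (nrow(candidates) < 2L) stop_validation("need >= 2 candidates to eliminate")
  validate_rfu(matrix)
  ks_d <- stats::setNames(candidates$ks_d, candidates$analyte_id)
  current <- candidates$analyte_id
  lx <- log2(matrix[, current, drop = FALSE])

  fit_size <- function(markers) {
    cfg <- config
    cfg$seed <- substream_seed(config$seed, sprintf("elim%03d", length(markers)))
    train_forest(lx[, markers, drop = FALSE], labels, cfg)
  }

  trace <- list()
  while (length(current) >= 1L) {
    f <- fit_size(current)
    if (length(current) > 1L) {
      imp <- f$importance
      ord <- order(imp, ks_d[names(imp)], names(imp))  # least important first
      removed <- names(imp)[ord[1]]
    } else removed <- NA_character_
    trace[[length(trace) + 1L]] <- data.frame(
      size = length(current), oob_auc = f$oob_auc, marker_removed = removed,
      panel = paste(current, collapse = ";"), stringsAsFactors = FALSE)
    if (length(current) == 1L) break
    current <- setdiff(current, removed)
  }
  trace <- do.call(rbind, trace)

  best <- max(trace$oob_auc)
  ok <- trace$size[trace$oob_auc >= best - tolerance]
  final_size <- min(ok)
  final_panel <- strsplit(trace$panel[trace$size == final_size], ";")[[1]]
  final_forest <- fit_size(final_panel)

  structure(list(marker_panel = final_panel,
                 forest = final_forest,
                 threshold = threshold,
                 elimination_trace = trace,
                 config = config,
                 tolerance = tolerance,
                 candidates = candidates),
            class = "marker_classifier")
}

#' Predict blinded case probabilities from an RFU matrix
#'
#' A pure function of the RFU matrix: annotations are never read, and the
#' output carries barcodes only (blinding contract). The call is `"case"`
#' iff the case vote fraction is at or above the classifier's fixed
#' threshold.
#'
#' @param object a `marker_classifier`.
#' @param matrix RFU matrix containing all panel markers (bridge formats
#'   first if the assay differs; see [bridge_formats()]).
#' @param ... unused.
#' @return data.frame: `barcode`, `probability`, `call`.
#' @export
predict.marker_classifier <- function(object, matrix, ...) {
  validate_rfu(matrix)
  missing_an <- setdiff(object$marker_panel, colnames(matrix))
  if (length(missing_an))
    stop_validation("panel markers missing from matrix: %s",
                    paste(missing_an, collapse = ", "))
  lx <- log2(matrix[, object$marker_panel, drop = FALSE])
  p <- stats::predict(object$forest$rf, as.data.frame(lx), type = "prob")[, "case"]
  data.frame(barcode = rownames(matrix),
             probability = as.numeric(p),
             call = ifelse(p >= object$threshold, "case", "control"),
             stringsAsFactors = FALSE)
}

#' Save / load a trained classifier archive
#'
#' The archive is a directory holding the panel, threshold and config as
#' plain text (json/csv) plus the fitted ensemble, so a frozen classifier
#' can be applied later to new cohorts without retraining.
#'
#' @param classifier a `marker_classifier`.
#' @param dir archive directory (created if needed).
#' @return [load_classifier()] returns the `marker_classifier`.
#' @export
save_classifier <- function(classifier, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(list(marker_panel = classifier$marker_panel,
                            threshold = classifier$threshold,
                            tolerance = classifier$tolerance,
                            config = unclass(classifier$config)),
                       file.path(dir, "model.json"), auto_unbox = TRUE, digits = NA)
  write.csv(classifier$elimination_trace, file.path(dir, "elimination_trace.csv"),
            row.names = FALSE)
  saveRDS(classifier, file.path(dir, "classifier.rds"))
  invisible(dir)
}

#' @rdname save_classifier
#' @export
load_classifier <- function(dir) {
  path <- file.path(dir, "classifier.rds")
  if (!file.exists(path)) stop_validation("no classifier archive at %s", dir)
  readRDS(path)
}
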