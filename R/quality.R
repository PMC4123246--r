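# Sample Mapping Vector (SMV) quality scoring. Three protein panels typify
# the blood components disturbed by sample handling: complement activation
# (4 proteins), cell contamination (30 intracellular leukocyte proteins
# released by lysis) and platelet activation/lysis (16 proteins). For serum
# only the complement and cell contamination panels are applicable, because
# platelets are consumed during clotting.

#' Construct an SMV panel set
#'
#' @param panels named list with elements `cell_contamination` (30 analyte
#'   ids), `complement` (4) and `platelet` (16).
#' @param matrix_type `"serum"` or `"plasma"`. For serum the platelet panel
#'   is never scored.
#' @return List of class `smv_panel_set`.
#' @export
smv_panel_set <- function(panels, matrix_type = c("serum", "plasma")) {
  matrix_type <- match.arg(matrix_type)
  expected <- SMV_PANEL_SIZES
  if (!setequal(names(panels), names(expected)))
    stop_validation("panels must be named %s", paste(names(expected), collapse = ", "))
  for (nm in names(expected)) {
    if (length(panels[[nm]]) != expected[[nm]])
      stop_validation("panel %s must have %d analytes, got %d",
                      nm, expected[[nm]], length(panels[[nm]]))
  }
  structure(list(panels = panels, matrix_type = matrix_type),
            class = "smv_panel_set")
}

applicable_panels <- function(panel_set) {
  nm <- names(panel_set$panels)
  if (panel_set$matrix_type == "serum") nm <- setdiff(nm, "platelet")
  nm
}

#' Read / write an SMV panel membership file
#'
#' The panel file is a two-column csv (`panel`, `analyte_id`); the shipped
#' default structure uses simulator analyte ids, and any real panel can be
#' substituted.
#'
#' @param path csv path.
#' @param panel_set an `smv_panel_set` (for writing).
#' @param matrix_type passed to [smv_panel_set()] when reading.
#' @return [read_smv_panels()] returns an `smv_panel_set`.
#' @export
read_smv_panels <- function(path, matrix_type = "serum") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("panel", "analyte_id") %in% names(df)))
    stop_validation("panel file must have columns panel, analyte_id")
  smv_panel_set(split(df$analyte_id, df$panel)[names(SMV_PANEL_SIZES)],
                matrix_type = matrix_type)
}

#' @rdname read_smv_panels
#' @export
write_smv_panels <- function(panel_set, path) {
  df <- do.call(rbind, lapply(names(panel_set$panels), function(nm)
    data.frame(panel = nm, analyte_id = panel_set$panels[[nm]])))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Compute per-sample SMV panel scores
#'
#' Each panel analyte is standardized to a robust z on the log2 scale,
#' `z = (log2 RFU - reference median) / (1.4826 * reference MAD)`, and a
#' sample's panel score is the median of its panel analytes' robust z. The
#' median-of-robust-z aggregate is monotone in contamination severity and
#' insensitive to single-analyte failures. Scores are invariant to any
#' per-sample scalar applied before median normalization.
#'
#' @param matrix normalized RFU matrix.
#' @param panels an `smv_panel_set`.
#' @param reference_barcodes barcodes defining the standardization
#'   reference, or `"all"`; at least 20 reference samples are required.
#' @return A `quality_assessment`: list with `scores` (data.frame, one row
#'   per sample, one column per applicable panel), `panels`, and the
#'   reference medians/MADs used. Categories are added by
#'   [classify_quality()].
#' @export
compute_smv_scores <- function(matrix, panels, reference_barcodes = "all") {
  validate_rfu(matrix)
  if (!inherits(panels, "smv_panel_set")) stop_validation("panels must be an smv_panel_set")
  use <- applicable_panels(panels)
  need <- unlist(panels$panels[use], use.names = FALSE)
  missing_an <- setdiff(need, colnames(matrix))
  if (length(missing_an))
    stop_validation("panel analytes missing from matrix: %s",
                    paste(missing_an, collapse = ", "))
  ref <- if (identical(reference_barcodes, "all")) rownames(matrix) else reference_barcodes
  if (length(setdiff(ref, rownames(matrix))))
    stop_validation("reference barcodes absent from matrix")
  if (length(ref) < 20L)
    stop_validation("need >= 20 reference samples for robust standardization, got %d",
                    length(ref))

  lx <- log2(matrix[, need, drop = FALSE])
  ref_med <- apply(lx[ref, , drop = FALSE], 2, median)
  ref_mad <- apply(lx[ref, , drop = FALSE], 2, mad)  # mad() includes 1.4826
  zero <- names(ref_mad)[ref_mad == 0]
  if (length(zero))
    stop_validation("zero reference MAD for analyte(s): %s", paste(zero, collapse = ", "))
  z <- sweep(sweep(lx, 2, ref_med), 2, ref_mad, `/`)

  scores <- data.frame(barcode = rownames(matrix), stringsAsFactors = FALSE)
  for (nm in use)
    scores[[nm]] <- apply(z[, panels$panels[[nm]], drop = FALSE], 1, median)
  structure(list(scores = scores, panels = panels,
                 reference = list(barcodes = ref, median = ref_med, mad = ref_mad)),
            class = "quality_assessment")
}

#' Classify samples as high or low collection quality
#'
#' A sample is high quality iff every applicable panel score is below its
#' cutoff; the composite score is the maximum over applicable panels (a
#' sample is flagged if any contamination mode is flagged). Cutoffs are
#' either fixed per panel, or derived empirically as `"empirical:q"`: the
#' common cutoff is placed so that a fraction `q` of the reference cohort
#' (by composite score, ties broken toward high quality) falls below it.
#'
#' @param assessment a `quality_assessment` from [compute_smv_scores()].
#' @param cutoffs named numeric (per applicable panel), a single number
#'   recycled to all panels (default 2 robust-z), or a string
#'   `"empirical:q"` with `q` in (0,1).
#' @return The assessment with `scores$composite`, `scores$category` and
#'   `cutoffs` filled in.
#' @export
#' @examples
#' # classify_quality(assessment, "empirical:0.8")   # 80/20 quality split
classify_quality <- function(assessment, cutoffs = 2) {
  if (!inherits(assessment, "quality_assessment"))
    stop_validation("assessment must come from compute_smv_scores()")
  use <- applicable_panels(assessment$panels)
  sc <- as.matrix(assessment$scores[, use, drop = FALSE])
  composite <- apply(sc, 1, max)

  if (is.character(cutoffs) && grepl("^empirical:", cutoffs)) {
    q <- suppressWarnings(as.numeric(sub("^empirical:", "", cutoffs)))
    if (is.na(q) || q <= 0 || q >= 1)
      stop_validation("empirical quantile must be in (0, 1)")
    n <- length(composite)
    k <- ceiling(q * n)
    v <- sort(composite)
    # cutoff = smallest composite value strictly above the k-th order
    # statistic, so samples tied at the boundary are kept as high quality
    above <- v[v > v[k]]
    cut_val <- if (length(above)) above[1] else Inf
    cutoffs <- stats::setNames(rep(cut_val, length(use)), use)
  } else if (is.numeric(cutoffs)) {
    if (length(cutoffs) == 1L) cutoffs <- stats::setNames(rep(cutoffs, length(use)), use)
    if (!all(use %in% names(cutoffs)))
      stop_validation("cutoffs must be named for panels: %s", paste(use, collapse = ", "))
    cutoffs <- cutoffs[use]
  } else {
    stop_validation("cutoffs must be numeric or \"empirical:q\"")
  }

  high <- rep(TRUE, nrow(sc))
  for (nm in use) high <- high & (sc[, nm] < cutoffs[[nm]])
  assessment$scores$composite <- composite
  assessment$scores$category <- ifelse(high, "high", "low")
  assessment$cutoffs <- cutoffs
  assessment
}

#' Site-level consistency and case/control collection-bias report
#'
#' Two diagnostics for preanalytic confounding. Per analyte: control-group
#' medians per site and the maximum pairwise fold change between sites (a
#' marker whose control distribution shifts more than ~1.5-2 fold between
#' collection sites is suspect). Per site: the case-minus-control shift of
#' the composite SMV score with a rank-sum p-value (a low p-value means the
#' site collected case and control blood differently, the most dangerous
#' form of bias).
#'
#' @param matrix normalized RFU matrix.
#' @param annotations sample annotations with `site` and `group`.
#' @param analyte_ids analytes to report site folds for.
#' @param assessment optional classified `quality_assessment`; needed for
#'   the per-site case/control SMV shift.
#' @param min_controls sites with fewer control samples are excluded (with
#'   a warning) from the fold computation.
#' @return A `site_bias_report`: list with `analyte_folds` (data.frame:
#'   analyte_id, max_site_fold, site_hi, site_lo) and `site_bias`
#'   (data.frame: site, smv_shift, p_value; `NULL` without an assessment).
#' @export
site_consistency <- function(matrix, annotations, analyte_ids,
                             assessment = NULL, min_controls = 5L) {
  validate_rfu(matrix)
  missing_an <- setdiff(analyte_ids, colnames(matrix))
  if (length(missing_an))
    stop_validation("analytes missing from matrix: %s", paste(missing_an, collapse = ", "))
  ctrl <- annotations$group == "control"
  keep_sites <- character(0)
  for (s in unique(annotations$site)) {
    if (sum(ctrl & annotations$site == s) >= min_controls) keep_sites <- c(keep_sites, s)
    else warning(sprintf("site %s excluded from fold computation (<%d controls)",
                         s, min_controls))
  }
  if (length(keep_sites) < 2L)
    stop_validation("need >= 2 sites with >= %d controls each", min_controls)

  folds <- data.frame(analyte_id = analyte_ids, max_site_fold = NA_real_,
                      site_hi = NA_character_, site_lo = NA_character_,
                      stringsAsFactors = FALSE)
  for (i in seq_along(analyte_ids)) {
    med <- vapply(keep_sites, function(s)
      median(matrix[annotations$barcode[ctrl & annotations$site == s], analyte_ids[i]]),
      numeric(1))
    folds$max_site_fold[i] <- max(med) / min(med)
    folds$site_hi[i] <- keep_sites[which.max(med)]
    folds$site_lo[i] <- keep_sites[which.min(med)]
  }

  site_bias <- NULL
  if (!is.null(assessment)) {
    if (is.null(assessment$scores$composite))
      stop_validation("assessment must be classified (composite score missing)")
    comp <- stats::setNames(assessment$scores$composite, assessment$scores$barcode)
    rows <- lapply(unique(annotations$site), function(s) {
      ca <- comp[annotations$barcode[annotations$site == s & annotations$group == "case"]]
      co <- comp[annotations$barcode[annotations$site == s & annotations$group == "control"]]
      if (length(ca) == 0 || length(co) == 0) return(NULL)
      data.frame(site = s, smv_shift = median(ca) - median(co),
                 p_value = suppressWarnings(wilcox.test(ca, co)$p.value))
    })
    site_bias <- do.call(rbind, rows)
  }
  structure(list(analyte_folds = folds, site_bias = site_bias),
            class = "site_bias_report")
}
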