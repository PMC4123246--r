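# Standard preprocessing for affinity-proteomic RFU matrices: per-sample
# median normalization, calibrator-based per-analyte plate scaling, and
# per-analyte bridging between assay formats.

#' Median-normalize an RFU matrix
#'
#' Aligns the median of each sample to a common reference by a per-sample
#' multiplicative scale factor, the conventional first normalization step
#' for RFU matrices. With `reference = "auto"` the reference is the median
#' of the per-sample medians, which makes the operation idempotent and free
#' of any external reference file.
#'
#' @param matrix RFU matrix.
#' @param reference positive scalar reference median, or `"auto"`.
#' @param exclude analyte ids excluded from the per-sample median
#'   computation (they are still scaled). Excluding analytes known to
#'   respond to collection quality (the SMV panels) keeps a contaminated
#'   sample's scale factor from dragging its clean analytes down; with a
#'   full-size menu the panels are a small minority and this matters
#'   little, but on reduced menus it prevents contamination from leaking
#'   into unrelated analytes through normalization.
#' @return A `normalization_result`: list with `matrix` (normalized),
#'   `sample_scale_factors` (named per barcode), `reference_median`, and
#'   `reference_medians` (per-analyte medians of the normalized matrix,
#'   useful as downstream calibration references).
#' @export
#' @examples
#' m <- matrix(c(1, 2, 3, 2, 4, 6), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("a", "b"), c("x", "y", "z")))
#' median_normalize(m, reference = 4)$matrix
median_normalize <- function(matrix, reference = "auto", exclude = character()) {
  validate_rfu(matrix)
  use <- setdiff(colnames(matrix), exclude)
  if (length(use) < 2L)
    stop_validation("median normalization needs >= 2 non-excluded analytes")
  row_med <- apply(matrix[, use, drop = FALSE], 1, median)
  ref <- if (identical(reference, "auto")) median(row_med) else reference
  if (!is.numeric(ref) || length(ref) != 1L || !is.finite(ref) || ref <= 0)
    stop_validation("reference median must be a positive scalar or \"auto\"")
  fac <- ref / row_med
  out <- matrix * fac
  structure(list(matrix = out,
                 sample_scale_factors = stats::setNames(fac, rownames(matrix)),
                 reference_median = ref,
                 reference_medians = apply(out, 2, median)),
            class = "normalization_result")
}

#' Calibrate analytes across plates using reference calibrator wells
#'
#' Applies a multiplicative scaling coefficient per analyte (per plate, if a
#' plate assignment is given) computed from replicate calibrator wells:
#' factor = reference value / median of the calibrator wells for that
#' analyte. When no external reference is supplied, the per-analyte median
#' across all calibrator wells in the run is used, which aligns plates to
#' each other.
#'
#' @param matrix RFU matrix containing both study and calibrator wells.
#' @param calibrator_barcodes barcodes of the calibrator wells.
#' @param reference_values optional named positive vector, one per analyte.
#' @param plates optional named character vector mapping every barcode to a
#'   plate; factors are then computed and applied per plate.
#' @return A `calibration_result`: list with `matrix` (calibrated) and
#'   `analyte_scale_factors` (matrix, plates x analytes).
#' @export
plate_calibrate <- function(matrix, calibrator_barcodes, reference_values = NULL,
                            plates = NULL) {
  validate_rfu(matrix)
  missing_bc <- setdiff(calibrator_barcodes, rownames(matrix))
  if (length(missing_bc))
    stop_validation("calibrator barcodes absent from matrix: %s",
                    paste(missing_bc, collapse = ", "))
  if (length(calibrator_barcodes) < 1L)
    stop_validation("at least one calibrator barcode is required")
  if (is.null(plates)) {
    plates <- stats::setNames(rep("plate1", nrow(matrix)), rownames(matrix))
  } else if (!all(rownames(matrix) %in% names(plates))) {
    stop_validation("plates must be named for every barcode")
  }
  if (is.null(reference_values)) {
    reference_values <- apply(matrix[calibrator_barcodes, , drop = FALSE], 2, median)
  }
  if (!all(colnames(matrix) %in% names(reference_values)))
    stop_validation("reference_values must cover every analyte")
  reference_values <- reference_values[colnames(matrix)]
  if (any(reference_values <= 0)) stop_validation("reference values must be positive")

  plate_ids <- unique(plates[rownames(matrix)])
  fac <- matrix(NA_real_, length(plate_ids), ncol(matrix),
                dimnames = list(plate_ids, colnames(matrix)))
  out <- matrix
  for (pl in plate_ids) {
    wells <- intersect(calibrator_barcodes, rownames(matrix)[plates[rownames(matrix)] == pl])
    if (length(wells) == 0L)
      stop_validation("plate %s has no calibrator wells", pl)
    cal_med <- apply(matrix[wells, , drop = FALSE], 2, median)
    fac[pl, ] <- reference_values / cal_med
    rows <- plates[rownames(matrix)] == pl
    out[rows, ] <- sweep(matrix[rows, , drop = FALSE], 2, fac[pl, ], `*`)
  }
  structure(list(matrix = out, analyte_scale_factors = fac),
            class = "calibration_result")
}

#' Bridge a new assay format onto the scale of a frozen classifier
#'
#' When a validation cohort is assayed in a different format (for example a
#' reduced panel assay), a subset of samples re-assayed in both formats
#' yields per-analyte bridging factors — the median over paired samples of
#' the old/new RFU ratio — that place the new-format data on the old scale,
#' so a frozen classifier applies unchanged.
#'
#' @param paired_old,paired_new RFU matrices of the same samples assayed in
#'   the old and new format (shared barcodes; at least 3 required).
#' @param target new-format RFU matrix to bridge.
#' @return The target matrix restricted to the bridgeable analytes, on the
#'   old-format scale.
#' @export
bridge_formats <- function(paired_old, paired_new, target) {
  validate_rfu(paired_old); validate_rfu(paired_new); validate_rfu(target)
  shared_bc <- intersect(rownames(paired_old), rownames(paired_new))
  if (length(shared_bc) < 3L)
    stop_validation("bridging needs >= 3 paired samples; found %d", length(shared_bc))
  shared_an <- Reduce(intersect, list(colnames(paired_old), colnames(paired_new),
                                      colnames(target)))
  if (length(shared_an) == 0L)
    stop_validation("no analytes shared between formats")
  ratio <- paired_old[shared_bc, shared_an, drop = FALSE] /
    paired_new[shared_bc, shared_an, drop = FALSE]
  fac <- apply(ratio, 2, median)
  out <- sweep(target[, shared_an, drop = FALSE], 2, fac, `*`)
  attr(out, "bridging_factors") <- fac
  out
}
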