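# Proteomic RFU matrices are plain numeric matrices: rows are samples keyed
# by barcode (rownames), columns are analytes (colnames). Values are strictly
# positive relative fluorescence units (RFU).

#' Validate a proteomic RFU matrix
#'
#' Checks the container invariants assumed throughout the package: a numeric
#' matrix with unique barcode rownames, unique analyte colnames, and strictly
#' positive finite values.
#'
#' @param x numeric matrix, samples x analytes, dimnames set.
#' @return `x`, invisibly, if valid; otherwise an error describing the first
#'   violated invariant (non-positive cells are reported by barcode and
#'   analyte).
#' @export
validate_rfu <- function(x) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_validation("RFU data must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop_validation("RFU matrix must carry barcode rownames and analyte colnames")
  if (anyDuplicated(rownames(x)))
    stop_validation("duplicate barcodes: %s",
                    paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (anyDuplicated(colnames(x)))
    stop_validation("duplicate analyte columns: %s",
                    paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  bad <- which(!is.finite(x) | x <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop_validation("non-positive or non-finite RFU at [barcode=%s, analyte=%s]%s",
                    rownames(x)[bad[1, 1]], colnames(x)[bad[1, 2]],
                    if (nrow(bad) > 1) sprintf(" (and %d more cells)", nrow(bad) - 1) else "")
  }
  invisible(x)
}

#' Write a cohort to delimited text files
#'
#' Persists an RFU matrix and its sample annotations as two UTF-8 csv files,
#' `<stem>_rfu.csv` (first column `barcode`, one column per analyte) and
#' `<stem>_meta.csv` (per-sample metadata). The layout mirrors the usual
#' supplementary-file format of affinity-proteomic studies.
#'
#' @param matrix RFU matrix (see [validate_rfu()]).
#' @param annotations data.frame with a `barcode` column matching the matrix
#'   rows one-to-one.
#' @param stem path prefix for the two output files.
#' @return The two file paths, invisibly.
#' @seealso [read_cohort()] for the inverse; the round trip is exact up to
#'   numeric printing precision (15 significant digits are written).
#' @export
write_cohort <- function(matrix, annotations, stem) {
  validate_rfu(matrix)
  if (!is.data.frame(annotations) || is.null(annotations$barcode))
    stop_validation("annotations must be a data.frame with a barcode column")
  if (!identical(as.character(annotations$barcode), rownames(matrix)))
    stop_validation("annotation barcodes must match matrix rows in order")
  rfu <- data.frame(barcode = rownames(matrix), check.names = FALSE)
  for (j in colnames(matrix)) rfu[[j]] <- format(matrix[, j], digits = 15, trim = TRUE)
  paths <- paste0(stem, c("_rfu.csv", "_meta.csv"))
  write.csv(rfu, paths[1], row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  write.csv(annotations, paths[2], row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}

#' Read a cohort from delimited text files
#'
#' Reads the `<stem>_rfu.csv` / `<stem>_meta.csv` pair written by
#' [write_cohort()] and re-validates all container invariants. Duplicated
#' barcodes or analyte columns and non-positive RFU cells are rejected with
#' the offending label in the error message.
#'
#' @param stem path prefix used when writing.
#' @return `list(matrix =, annotations =)`.
#' @export
read_cohort <- function(stem) {
  paths <- paste0(stem, c("_rfu.csv", "_meta.csv"))
  for (p in paths) if (!file.exists(p)) stop_validation("cohort file missing: %s", p)
  rfu <- read.csv(paths[1], check.names = FALSE, fileEncoding = "UTF-8")
  if (names(rfu)[1] != "barcode") stop_validation("%s: first column must be 'barcode'", paths[1])
  ana <- names(rfu)[-1]
  if (anyDuplicated(ana))
    stop_validation("duplicate analyte columns: %s",
                    paste(unique(ana[duplicated(ana)]), collapse = ", "))
  bc <- as.character(rfu$barcode)
  if (anyDuplicated(bc))
    stop_validation("duplicate barcodes: %s",
                    paste(unique(bc[duplicated(bc)]), collapse = ", "))
  m <- as.matrix(rfu[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- bc
  validate_rfu(m)
  meta <- read.csv(paths[2], check.names = FALSE, fileEncoding = "UTF-8",
                   stringsAsFactors = FALSE)
  if (is.null(meta$barcode)) stop_validation("%s: missing barcode column", paths[2])
  meta$barcode <- as.character(meta$barcode)
  if (!identical(meta$barcode, bc))
    stop_validation("metadata barcodes do not match RFU barcodes")
  list(matrix = m, annotations = meta)
}
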