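# Candidate marker discovery: two-sample KS tests on log2 RFU within the
# high-quality stratum, BH control, top-D ranking, then robustness filtering
# against the low-quality stratum, SMV correlation and cross-site folds.

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the supremum over thresholds of the absolute difference of the two
#' empirical CDFs; the two-sided p-value uses the asymptotic Kolmogorov
#' distribution with the standard effective sample size (ties, which are
#' rare on continuous RFU data, make the p-value conservative).
#'
#' @param x,y numeric samples, each of length >= 3.
#' @return `list(statistic = D, p_value =)`.
#' @export
#' @examples
#' ks_two_sample(c(1, 3, 5), c(2, 4, 6))$statistic  # 1/3
ks_two_sample <- function(x, y) {
  if (length(x) < 3L || length(y) < 3L)
    stop_validation("KS test needs >= 3 observations per group (got %d and %d)",
                    length(x), length(y))
  kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = kt$p.value)
}

#' Select candidate markers in the high-quality stratum
#'
#' Runs a two-sample KS test (case vs control, log2 RFU) per analyte using
#' only samples classified as high collection quality, applies
#' Benjamini-Hochberg control at `fdr_q`, ranks survivors by descending D
#' (ties by smaller p, then analyte id) and truncates to `max_candidates`.
#' Directions follow the sign of the case-minus-control median difference.
#'
#' @param matrix normalized RFU matrix.
#' @param annotations sample annotations (`barcode`, `group`).
#' @param quality classified `quality_assessment`; discovery is restricted
#'   to its high-quality samples. Pass `NULL` to deliberately skip quality
#'   stratification (ablation mode).
#' @param fdr_q BH false-discovery-rate threshold (default 0.05).
#' @param max_candidates cap on the candidate list (default 15).
#' @return data.frame of class `marker_candidates`: `analyte_id`,
#'   `direction`, `ks_d`, `p_value`, `q_value`, plus empty robustness
#'   columns filled by [robustness_filter()].
#' @export
select_candidates <- function(matrix, annotations, quality,
                              fdr_q = 0.05, max_candidates = 15L) {
  validate_rfu(matrix)
  keep <- annotations$barcode
  if (!is.null(quality)) {
    if (is.null(quality$scores$category))
      stop_validation("quality assessment must be classified")
    hq <- quality$scores$barcode[quality$scores$category == "high"]
    keep <- intersect(keep, hq)
  }
  ann <- annotations[annotations$barcode %in% keep, , drop = FALSE]
  case_bc <- ann$barcode[ann$group == "case"]
  ctrl_bc <- ann$barcode[ann$group == "control"]
  if (length(case_bc) < 10L || length(ctrl_bc) < 10L)
    stop_validation("discovery stratum too small: %d cases, %d controls (need >= 10 each)",
                    length(case_bc), length(ctrl_bc))

  lx <- log2(matrix)
  res <- data.frame(analyte_id = colnames(matrix), direction = NA_character_,
                    ks_d = NA_real_, p_value = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(ncol(lx))) {
    kt <- ks_two_sample(lx[case_bc, i], lx[ctrl_bc, i])
    res$ks_d[i] <- kt$statistic
    res$p_value[i] <- kt$p_value
    res$direction[i] <- if (median(lx[case_bc, i]) >= median(lx[ctrl_bc, i])) "up" else "down"
  }
  res$q_value <- p.adjust(res$p_value, method = "BH")
  res <- res[res$q_value <= fdr_q, , drop = FALSE]
  res <- res[order(-res$ks_d, res$p_value, res$analyte_id), , drop = FALSE]
  res <- head(res, max_candidates)
  rownames(res) <- NULL
  for (col in c("auc_high", "auc_low", "max_site_fold",
                "max_abs_smv_correlation"))
    res[[col]] <- rep(NA_real_, nrow(res))
  res$passes_robustness <- rep(NA, nrow(res))
  class(res) <- c("marker_candidates", "data.frame")
  res
}

#' Filter candidate markers for robustness to preanalytic variation
#'
#' A candidate passes iff all three diagnostics hold: (a) its maximum
#' absolute Spearman correlation with any applicable SMV panel score,
#' computed over control samples only, is below `r_max` (restricting to
#' controls isolates the marker's response to collection quality: when
#' disease status and collection quality are themselves confounded, a
#' pooled correlation would indict genuine disease markers); (b) its
#' case/control discrimination in the low-quality
#' stratum retains, in the same direction, at least `retain_frac` of the
#' above-chance discrimination it showed in the high-quality stratum
#' (`auc_low - 0.5 >= retain_frac * (auc_high - 0.5)` after orienting both
#' by the candidate's direction); (c) its maximum control-group fold change
#' between collection sites is at most `fold_max`. All diagnostics are
#' recorded whether passed or not.
#'
#' @param candidates `marker_candidates` from [select_candidates()].
#' @param matrix normalized RFU matrix.
#' @param annotations sample annotations (`barcode`, `group`, `site`).
#' @param quality classified `quality_assessment` defining the strata and
#'   providing the panel scores.
#' @param r_max,retain_frac,fold_max thresholds for (a), (b), (c); the
#'   defaults 0.3 / 0.6 / 1.5 are deliberately strict, since a marker that
#'   tracks contamination or drifts across sites will not validate.
#' @return The candidates with diagnostics and `passes_robustness` filled.
#' @export
robustness_filter <- function(candidates, matrix, annotations, quality,
                              r_max = 0.3, retain_frac = 0.6, fold_max = 1.5) {
  validate_rfu(matrix)
  if (is.null(quality$scores$category))
    stop_validation("quality assessment must be classified")
  if (is.null(annotations$site)) stop_validation("annotations must carry site labels")
  if (nrow(candidates) == 0L) return(candidates)

  sc <- quality$scores
  panels <- applicable_panels(quality$panels)
  low_bc <- sc$barcode[sc$category == "low"]
  high_bc <- sc$barcode[sc$category == "high"]
  if (length(low_bc) == 0L)
    stop_validation("low-quality stratum is empty; robustness cannot be assessed")

  lx <- log2(matrix[, candidates$analyte_id, drop = FALSE])
  grp <- stats::setNames(annotations$group, annotations$barcode)
  ctrl_bc <- intersect(sc$barcode, names(grp)[grp == "control"])
  folds <- site_consistency(matrix, annotations, candidates$analyte_id)$analyte_folds

  stratum_auc <- function(bc, analyte) {
    ca <- lx[intersect(bc, names(grp)[grp == "case"]), analyte]
    co <- lx[intersect(bc, names(grp)[grp == "control"]), analyte]
    if (length(ca) == 0L || length(co) == 0L) return(NA_real_)
    roc_auc(ca, co)
  }

  for (i in seq_len(nrow(candidates))) {
    a <- candidates$analyte_id[i]
    rho <- vapply(panels, function(nm)
      abs(cor(lx[ctrl_bc, a],
              sc[[nm]][match(ctrl_bc, sc$barcode)], method = "spearman")), numeric(1))
    candidates$max_abs_smv_correlation[i] <- max(rho)
    candidates$auc_high[i] <- stratum_auc(high_bc, a)
    candidates$auc_low[i] <- stratum_auc(low_bc, a)
    candidates$max_site_fold[i] <- folds$max_site_fold[folds$analyte_id == a]

    s <- if (candidates$direction[i] == "up") 1 else -1
    s_high <- s * (candidates$auc_high[i] - 0.5)
    s_low <- s * (candidates$auc_low[i] - 0.5)
    pass_a <- candidates$max_abs_smv_correlation[i] < r_max
    pass_b <- !is.na(s_low) && s_low >= retain_frac * s_high
    pass_c <- candidates$max_site_fold[i] <= fold_max
    candidates$passes_robustness[i] <- pass_a && pass_b && pass_c
  }
  candidates
}

#' Write a candidate table to csv
#' @param candidates `marker_candidates`.
#' @param path output csv path.
#' @export
write_candidates <- function(candidates, path) {
  write.csv(as.data.frame(candidates), path, row.names = FALSE)
  invisible(path)
}
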