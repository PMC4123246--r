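# Unblinded evaluation: ROC/AUC overall and per histology, stratified
# sensitivity/specificity with binomial confidence intervals, and
# prevalence-adjusted predictive values via Bayes' rule.

#' Area under the ROC curve (rank statistic)
#'
#' The Mann-Whitney probability that a random case scores above a random
#' control, with ties counted one half; identical to the area under the
#' empirical ROC curve.
#'
#' @param scores_cases,scores_controls numeric scores, each non-empty.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' roc_auc(c(0.7, 0.4), c(0.5, 0.3))  # 0.75
roc_auc <- function(scores_cases, scores_controls) {
  n1 <- length(scores_cases); n0 <- length(scores_controls)
  if (n1 == 0L || n0 == 0L)
    stop_validation("both groups must be non-empty (%d cases, %d controls)", n1, n0)
  r <- rank(c(scores_cases, scores_controls))
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Binomial proportion confidence interval
#'
#' Wilson score interval by default (it reproduces the usual whole-percent
#' intervals printed in diagnostic studies even at small n), with exact
#' Clopper-Pearson as an alternative.
#'
#' @param x successes, `n` trials.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @param method `"wilson"` or `"clopper-pearson"`.
#' @return `c(low, high)` on the proportion scale.
#' @export
binom_ci <- function(x, n, conf = 0.95, method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  if (x < 0 || n < 1 || x > n) stop_validation("need 0 <= x <= n, n >= 1")
  ci <- if (method == "wilson")
    suppressWarnings(prop.test(x, n, conf.level = conf, correct = FALSE)$conf.int)
  else binom.test(x, n, conf.level = conf)$conf.int
  as.numeric(ci)
}

#' Prevalence-adjusted predictive values by Bayes' rule
#'
#' `ppv = sens * prev / (sens * prev + (1 - spec) * (1 - prev))` and
#' `npv = spec * (1 - prev) / (spec * (1 - prev) + (1 - sens) * prev)`.
#' At the degenerate operating point sens = 0, spec = 1 (call everything
#' negative) the PPV is undefined (`NaN`) and the NPV equals `1 - prev`.
#'
#' @param sensitivity,specificity fractions in `[0, 1]`.
#' @param prevalence disease prevalence, strictly inside (0, 1).
#' @return `list(ppv =, npv =)`.
#' @export
#' @examples
#' ppv_npv(45/63, 51/72, 0.15)  # PPV ~0.30, NPV ~0.93
ppv_npv <- function(sensitivity, specificity, prevalence) {
  if (!is.finite(prevalence) || prevalence <= 0 || prevalence >= 1)
    stop_validation("prevalence must be in (0, 1)")
  for (v in c(sensitivity, specificity))
    if (!is.finite(v) || v < 0 || v > 1)
      stop_validation("sensitivity and specificity must be in [0, 1]")
  ppv <- sensitivity * prevalence /
    (sensitivity * prevalence + (1 - specificity) * (1 - prevalence))
  npv <- specificity * (1 - prevalence) /
    (specificity * (1 - prevalence) + (1 - sensitivity) * prevalence)
  list(ppv = ppv, npv = npv)
}

#' Stratified diagnostic performance of unblinded predictions
#'
#' Joins predictions to unblinded labels by barcode and computes: per-stratum
#' sensitivity for histology (AD, SQ) by stage group (I, II-IV) and
#' specificity for the benign-nodule and all-control groups, each with a 95
#' percent confidence interval; AUC overall and per histology (cases of one
#' histology against all controls); and PPV/NPV for each requested
#' prevalence, overall and per histology. Percentages are rounded half-up
#' to whole percent for presentation.
#'
#' @param predictions data.frame from [predict.marker_classifier()]
#'   (`barcode`, `probability`, `call`).
#' @param annotations unblinded annotations (`barcode`, `group`,
#'   `histology`, `stage`, `control_subtype`).
#' @param prevalences numeric vector of assumed disease prevalences for
#'   predictive values (default 0.15 and 0.075).
#' @param ci_method `"wilson"` or `"clopper-pearson"`.
#' @return List of class `stratified_performance`: `strata` (data.frame
#'   with stratum, type, x, n, proportion, pct, ci_low_pct, ci_high_pct),
#'   `auc` (data.frame histology/auc), `predictive` (data.frame prevalence,
#'   histology, sensitivity, specificity, ppv, npv).
#' @export
stratified_performance <- function(predictions, annotations,
                                   prevalences = c(0.15, 0.075),
                                   ci_method = "wilson") {
  unmatched <- setdiff(predictions$barcode, annotations$barcode)
  if (length(unmatched))
    stop_validation("predictions with no matching annotation: %s",
                    paste(unmatched, collapse = ", "))
  d <- merge(predictions, annotations, by = "barcode")
  is_case <- d$group == "case"

  stratum_row <- function(name, type, sel, correct) {
    n <- sum(sel)
    if (n == 0L) {
      warning(sprintf("stratum %s is empty; omitted", name))
      return(NULL)
    }
    x <- sum(sel & correct)
    ci <- binom_ci(x, n, method = ci_method)
    data.frame(stratum = name, type = type, x = x, n = n,
               proportion = x / n,
               pct = round_half_up(100 * x / n),
               ci_low_pct = round_half_up(100 * ci[1]),
               ci_high_pct = round_half_up(100 * ci[2]),
               stringsAsFactors = FALSE)
  }

  rows <- list()
  called_case <- d$call == "case"
  for (h in c("AD", "SQ")) {
    rows[[length(rows) + 1L]] <- stratum_row(
      sprintf("stage_I_%s", h), "sensitivity",
      is_case & d$histology == h & d$stage == "I", called_case)
    rows[[length(rows) + 1L]] <- stratum_row(
      sprintf("stage_II-IV_%s", h), "sensitivity",
      is_case & d$histology == h & d$stage %in% c("II", "III", "IV"), called_case)
  }
  rows[[length(rows) + 1L]] <- stratum_row(
    "benign_nodule", "specificity",
    !is_case & d$control_subtype == "benign_nodule", !called_case)
  rows[[length(rows) + 1L]] <- stratum_row(
    "all_controls", "specificity", !is_case, !called_case)
  strata <- do.call(rbind, rows)

  auc_rows <- list(data.frame(histology = "all",
                              auc = roc_auc(d$probability[is_case],
                                            d$probability[!is_case])))
  for (h in c("AD", "SQ")) {
    ca <- d$probability[is_case & d$histology == h]
    if (length(ca))
      auc_rows[[length(auc_rows) + 1L]] <-
        data.frame(histology = h, auc = roc_auc(ca, d$probability[!is_case]))
  }
  auc <- do.call(rbind, auc_rows)

  spec_all <- sum(!is_case & !called_case) / sum(!is_case)
  pred_rows <- list()
  for (prev in prevalences) for (h in c("all", "AD", "SQ")) {
    sel <- if (h == "all") is_case else is_case & d$histology == h
    if (!any(sel)) next
    sens <- sum(sel & called_case) / sum(sel)
    pv <- ppv_npv(sens, spec_all, prev)
    pred_rows[[length(pred_rows) + 1L]] <-
      data.frame(prevalence = prev, histology = h, sensitivity = sens,
                 specificity = spec_all, ppv = pv$ppv, npv = pv$npv)
  }
  predictive <- do.call(rbind, pred_rows)

  structure(list(strata = strata, auc = auc, predictive = predictive,
                 ci_method = ci_method),
            class = "stratified_performance")
}

#' Write a performance report
#'
#' Emits `performance_strata.csv` (stratum, estimate and CI in whole
#' percent), `performance_auc.csv`, `performance_predictive.csv` and a
#' short markdown summary. Idempotent: re-running overwrites identical
#' content.
#'
#' @param performance a `stratified_performance`.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_performance_report <- function(performance, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(performance$strata, file.path(dir, "performance_strata.csv"),
            row.names = FALSE)
  write.csv(performance$auc, file.path(dir, "performance_auc.csv"),
            row.names = FALSE)
  write.csv(performance$predictive, file.path(dir, "performance_predictive.csv"),
            row.names = FALSE)
  md <- c("# Classifier performance", "",
          sprintf("CI method: %s", performance$ci_method), "",
          "## AUC by histology", "",
          sprintf("- %s: %.3f", performance$auc$histology, performance$auc$auc), "",
          "## Stratified sensitivity / specificity (% with 95% CI)", "",
          sprintf("- %s (%s): %d%% (%d-%d), %d/%d",
                  performance$strata$stratum, performance$strata$type,
                  performance$strata$pct, performance$strata$ci_low_pct,
                  performance$strata$ci_high_pct,
                  performance$strata$x, performance$strata$n))
  writeLines(md, file.path(dir, "performance_report.md"))
  invisible(dir)
}
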