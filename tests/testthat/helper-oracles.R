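# Independent oracles used to cross-check the implementation.

# Brute-force two-sample KS statistic: sweep every pooled value as a
# threshold and take the largest empirical-CDF gap.
brute_force_ks_d <- function(x, y) {
  max(vapply(c(x, y), function(t)
    abs(mean(x <= t) - mean(y <= t)), numeric(1)))
}

# Trapezoidal area under the empirical ROC curve (threshold sweep),
# independent of the rank-statistic formula.
trapezoid_auc <- function(cases, controls) {
  th <- sort(unique(c(cases, controls)), decreasing = TRUE)
  tpr <- c(0, vapply(th, function(t) mean(cases >= t), numeric(1)))
  fpr <- c(0, vapply(th, function(t) mean(controls >= t), numeric(1)))
  sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
}

# Closed-form AUC for two equal-variance normals separated by delta_mu.
normal_model_auc <- function(delta_mu, sd) pnorm(delta_mu / (sd * sqrt(2)))
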