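# Multi-site case/control cohort simulator. Log2 RFU for sample s, analyte a:
#   base_a + biological noise + disease term (histology fold x stage factor)
#   + lysis_loading_a * latent_contamination_s + assay noise (log-normal CV)
# Latent contamination severity is drawn per sample from a site-scaled
# log-normal and optionally shifted upward for cases (collection bias).

STAGE_FACTORS <- c(I = 1.0, II = 1.25, III = 1.5, IV = 1.75)

#' Construct a cohort design
#'
#' @param counts data.frame with columns `site`, `group` (case/control),
#'   `histology` (AD/SQ/none), `stage` (I-IV or none), `control_subtype`
#'   (smoker/benign_nodule/none) and `n` (subjects per cell).
#' @param site_contamination_scale named positive numeric, per-site scale of
#'   the latent contamination severity distribution.
#' @param casecontrol_bias named numeric, per-site additive shift of
#'   contamination severity applied to cases only (collection bias; 0 means
#'   cases and controls are collected identically at that site).
#' @param assay_cv technical coefficient of variation of the assay
#'   (default 0.05, i.e. the <5 percent regime of modern aptamer assays).
#' @param contamination_sdlog log-sd of the latent severity distribution.
#' @param seed integer seed recorded in the design.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(counts, site_contamination_scale, casecontrol_bias,
                          assay_cv = 0.05, contamination_sdlog = 0.6,
                          seed = 1L) {
  req <- c("site", "group", "histology", "stage", "control_subtype", "n")
  if (!is.data.frame(counts) || !all(req %in% names(counts)))
    stop_validation("counts must have columns: %s", paste(req, collapse = ", "))
  if (any(!is.finite(counts$n)) || any(counts$n < 0))
    stop_validation("counts must be non-negative and finite")
  if (sum(counts$n) == 0) stop_validation("design is empty: all counts are zero")
  bad_stage <- setdiff(unique(counts$stage), c("I", "II", "III", "IV", "none"))
  if (length(bad_stage)) stop_validation("invalid stage labels: %s", paste(bad_stage, collapse = ", "))
  if (!is.finite(assay_cv) || assay_cv <= 0 || assay_cv >= 1)
    stop_validation("assay_cv must be in (0, 1)")
  sites <- unique(counts$site)
  for (nm in c("site_contamination_scale", "casecontrol_bias")) {
    v <- get(nm)
    if (!all(sites %in% names(v)) || any(!is.finite(v)))
      stop_validation("%s must be finite and named for every site", nm)
  }
  if (any(site_contamination_scale <= 0))
    stop_validation("site_contamination_scale must be positive")
  structure(list(counts = counts,
                 site_contamination_scale = site_contamination_scale,
                 casecontrol_bias = casecontrol_bias,
                 assay_cv = assay_cv,
                 contamination_sdlog = contamination_sdlog,
                 seed = as.integer(seed)),
            class = "cohort_design")
}

# Spread a total count across sites as evenly as possible (deterministic).
spread_sites <- function(n, sites, offset = 0L) {
  k <- length(sites)
  base <- rep(n %/% k, k)
  r <- n %% k
  if (r > 0) base[((offset + seq_len(r) - 1L) %% k) + 1L] <- base[((offset + seq_len(r) - 1L) %% k) + 1L] + 1L
  stats::setNames(base, sites)
}

#' Default four-site training cohort design
#'
#' A 363-subject, 4-site design matching the size and composition of a
#' typical multi-centre NSCLC serum discovery cohort: 94 cases (64 AD with
#' stages I-IV 27/7/19/11; 30 SQ with stages 11/5/12/2) and 269 controls
#' (122 benign pulmonary nodule, 147 long-term smokers), spread as evenly as
#' possible over sites NYU, PITT, RPCI and BS. Site contamination scales are
#' heterogeneous, so sites differ in typical collection quality; with the
#' default SMV cutoff of 2 robust-z roughly 80 percent of samples score as
#' high quality.
#'
#' @param seed integer seed stored in the design.
#' @param confounded logical; if `TRUE`, two of the four sites collect case
#'   samples with systematically higher contamination severity than their
#'   controls (`casecontrol_bias` 1.5), planting the site-level case/control
#'   collection bias that turns contamination-responsive analytes into
#'   convincing decoy markers.
#' @param bias additive case-only contamination shift used when
#'   `confounded = TRUE`.
#' @return A `cohort_design`.
#' @export
default_training_design <- function(seed = 1L, confounded = FALSE, bias = 1.5) {
  sites <- c("NYU", "PITT", "RPCI", "BS")
  cells <- list(
    list(group = "case", histology = "AD", stage = c(I = 27, II = 7, III = 19, IV = 11)),
    list(group = "case", histology = "SQ", stage = c(I = 11, II = 5, III = 12, IV = 2)))
  rows <- list(); off <- 0L
  for (cl in cells) for (st in names(cl$stage)) {
    per <- spread_sites(cl$stage[[st]], sites, off); off <- off + 1L
    rows[[length(rows) + 1L]] <- data.frame(site = sites, group = cl$group,
                                            histology = cl$histology, stage = st,
                                            control_subtype = "none", n = as.integer(per))
  }
  ctrl <- c(benign_nodule = 122L, smoker = 147L)
  for (sub in names(ctrl)) {
    per <- spread_sites(ctrl[[sub]], sites, off); off <- off + 1L
    rows[[length(rows) + 1L]] <- data.frame(site = sites, group = "control",
                                            histology = "none", stage = "none",
                                            control_subtype = sub, n = as.integer(per))
  }
  counts <- do.call(rbind, rows)
  counts <- counts[counts$n > 0, , drop = FALSE]
  scale <- c(NYU = 0.35, PITT = 0.65, RPCI = 0.45, BS = 0.8)
  bvec <- c(NYU = 0, PITT = 0, RPCI = 0, BS = 0)
  if (confounded) bvec <- c(NYU = 0, PITT = bias, RPCI = 0, BS = bias)
  cohort_design(counts, scale, bvec, seed = seed)
}

#' Simulate a multi-site case/control proteomic cohort
#'
#' Draws a cohort from the generative model described in the package
#' vignette: log-normal biological variation around each analyte's baseline,
#' a multiplicative disease effect graded by histology and stage (stage
#' factors 1, 1.25, 1.5, 1.75 for I-IV) and switched on per case with the
#' marker's expression probability, a per-sample latent contamination
#' severity scaled by site (shifted for cases where collection bias is
#' planted) that drives SMV-panel and decoy analytes through their
#' `lysis_loading`, and log-normal assay noise at the design CV.
#'
#' @param menu an `analyte_menu` from [generate_analyte_menu()].
#' @param design a `cohort_design`.
#' @return `list(matrix =, annotations =)`; annotations retain the simulated
#'   truth field `latent_contamination`.
#' @export
#' @examples
#' menu <- generate_analyte_menu(120, seed = 1)
#' cohort <- simulate_cohort(menu, default_training_design(seed = 1))
#' dim(cohort$matrix)
simulate_cohort <- function(menu, design) {
  if (!inherits(menu, "analyte_menu")) stop_validation("menu must be an analyte_menu")
  if (!inherits(design, "cohort_design")) stop_validation("design must be a cohort_design")
  counts <- design$counts[design$counts$n > 0, , drop = FALSE]
  if (nrow(counts) == 0) stop_validation("design is empty")

  set.seed(substream_seed(design$seed, "cohort"))
  idx <- rep(seq_len(nrow(counts)), counts$n)
  n <- length(idx)
  ann <- data.frame(barcode = sprintf("BC%05d", seq_len(n)),
                    site = counts$site[idx],
                    group = counts$group[idx],
                    histology = counts$histology[idx],
                    stage = counts$stage[idx],
                    control_subtype = counts$control_subtype[idx],
                    stringsAsFactors = FALSE)
  ann$pack_years <- round(pmax(0, rnorm(n, 40, 15)), 1)

  scale <- design$site_contamination_scale[ann$site]
  latent <- rlnorm(n, meanlog = log(scale), sdlog = design$contamination_sdlog)
  latent <- latent + ifelse(ann$group == "case", design$casecontrol_bias[ann$site], 0)
  ann$latent_contamination <- pmax(latent, 0)

  is_case <- ann$group == "case"
  sf <- ifelse(is_case, STAGE_FACTORS[ann$stage], 0)
  sf[is.na(sf)] <- 0
  is_ad <- is_case & ann$histology == "AD"
  is_sq <- is_case & ann$histology == "SQ"

  asd <- cv_to_log2_sd(design$assay_cv)
  p <- nrow(menu)
  m <- matrix(0, nrow = n, ncol = p, dimnames = list(ann$barcode, menu$analyte_id))
  l2a <- log2(menu$disease_fold_ad); l2s <- log2(menu$disease_fold_sq)
  ep <- if (is.null(menu$expression_prob)) rep(1, p) else menu$expression_prob
  bf <- if (is.null(menu$benign_fold)) rep(1, p) else menu$benign_fold
  is_benign <- ann$group == "control" & ann$control_subtype == "benign_nodule"
  for (a in seq_len(p)) {
    expressed <- ifelse(is_case, stats::rbinom(n, 1, ep[a]), 0)
    delta <- expressed * sf * (is_ad * l2a[a] + is_sq * l2s[a]) +
      is_benign * log2(bf[a])
    x <- menu$base_log2_mean[a] +
      rnorm(n, 0, menu$biological_sd_log2[a]) +
      delta +
      menu$lysis_loading[a] * ann$latent_contamination +
      rnorm(n, 0, asd)
    m[, a] <- 2^x
  }
  validate_rfu(m)
  list(matrix = m, annotations = ann)
}
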