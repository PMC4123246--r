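# Analyte menu: the per-analyte ground truth of the simulator. Roles:
#   true_marker       disease effect, no contamination response
#   confounded_marker responds to collection contamination (decoy; may also
#                     carry a genuine disease effect, HSP90-style)
#   smv_cell / smv_complement / smv_platelet
#                     contamination signature panels (30 / 4 / 16 analytes)
#   noise             neither disease nor contamination

SMV_PANEL_SIZES <- c(cell_contamination = 30L, complement = 4L, platelet = 16L)

#' Generate a ground-truth analyte menu for cohort simulation
#'
#' Builds the per-analyte specification table used by [simulate_cohort()].
#' The menu always contains the full SMV signature structure (30 cell
#' contamination, 4 complement, 16 platelet analytes), `n_true` genuine
#' disease markers with zero contamination response, `n_confounded` decoy
#' markers that respond to contamination severity, and noise analytes for
#' the remainder.
#'
#' True-marker effects are specified as case/control fold changes per tumour
#' histology; squamous (SQ) effects are at least as large as adenocarcinoma
#' (AD) effects in absolute log2 magnitude, and down-markers mirror the
#' up-marker folds reciprocally. With `n_true <= 7` the true markers take the
#' names of well-known serum NSCLC markers (MMP12, SERPINA3, MMP7, C9, CRP
#' up; CNDP1, CA6 down) purely for readability of simulator output.
#'
#' @param n_analytes total number of analytes; must leave room for the 50 SMV
#'   analytes plus the requested markers.
#' @param n_true number of planted genuine disease markers.
#' @param n_confounded number of planted contamination-responsive decoys.
#' @param seed integer; the menu is deterministic given the seed.
#' @param fold_ad,fold_sq case/control fold change of up-markers for AD and
#'   SQ histology (SQ >= AD, elementwise); down-markers use the
#'   reciprocals. Scalars are recycled; vectors of length `n_true` give
#'   each marker its own effect size. The default is a 2-fold AD effect
#'   with the SQ effect `fold_ad^1.5` (about 2.8), the magnitude regime of
#'   validated serum markers; combined with the per-case expression
#'   probability this puts the simulated panel classifier in the
#'   AUC 0.85-0.95 range rather than at saturation.
#' @param confounded_fold_ad,confounded_fold_sq genuine disease fold carried
#'   by the decoys. The defaults (1.25 / 1.4) plant HSP90-style markers:
#'   genuinely associated with disease, yet also responsive to collection
#'   contamination, so a quality-blind analysis finds them compelling.
#' @param confounded_loading multiplicative log2 response of a decoy per unit
#'   latent contamination severity.
#' @param expression_prob probability that a given case expresses (sheds)
#'   a given true marker. Tumours are heterogeneous: a marker panel earns
#'   its size because different patients present different markers, so
#'   each true marker's disease effect is switched on per case with this
#'   probability (1 makes every marker fully penetrant).
#' @param benign_fold fold elevation of the acute-phase / inflammation
#'   markers (SERPINA3, C9, CRP in the canonical menu) in benign-nodule
#'   controls. Inflammatory nodules mimic part of the host-response
#'   signature, which is what makes them the clinically difficult control
#'   class and forces the classifier to rely on the full marker panel.
#' @return A data.frame of class `analyte_menu` with one row per analyte:
#'   `analyte_id`, `role`, `direction`, `disease_fold_ad`, `disease_fold_sq`,
#'   `lysis_loading`, `base_log2_mean`, `biological_sd_log2`.
#' @export
#' @examples
#' menu <- generate_analyte_menu(120, n_true = 7, n_confounded = 3, seed = 1)
#' table(menu$role)
generate_analyte_menu <- function(n_analytes, n_true = 7L, n_confounded = 3L,
                                  seed = 1L,
                                  fold_ad = NULL, fold_sq = NULL,
                                  confounded_fold_ad = 1.25,
                                  confounded_fold_sq = 1.4,
                                  confounded_loading = 0.9,
                                  expression_prob = 0.5,
                                  benign_fold = 1) {
  n_smv <- sum(SMV_PANEL_SIZES)
  need <- n_true + n_confounded + n_smv
  if (n_analytes < need)
    stop_validation("n_analytes=%d too small: need at least %d (%d short)",
                    n_analytes, need, need - n_analytes)
  if (is.null(fold_ad)) fold_ad <- 2
  if (is.null(fold_sq)) fold_sq <- fold_ad^1.5
  fold_ad <- rep_len(fold_ad, max(n_true, 1L))
  fold_sq <- rep_len(fold_sq, max(n_true, 1L))
  if (any(fold_sq < fold_ad))
    stop_validation("fold_sq must be >= fold_ad (SQ effects are the larger)")

  set.seed(substream_seed(seed, "menu"))
  canonical <- list(up = c("MMP12", "SERPINA3", "MMP7", "C9", "CRP"),
                    down = c("CNDP1", "CA6"))
  if (n_true <= 7L) {
    ids_true <- c(canonical$up, canonical$down)[seq_len(n_true)]
    dir_true <- c(rep("up", 5L), rep("down", 2L))[seq_len(n_true)]
  } else {
    ids_true <- sprintf("MARKER.%02d", seq_len(n_true))
    dir_true <- rep(c("up", "up", "down"), length.out = n_true)
  }
  ids <- c(ids_true,
           if (n_confounded > 0) sprintf("HSP90.%d", seq_len(n_confounded)),
           sprintf("CELL.%02d", seq_len(SMV_PANEL_SIZES[["cell_contamination"]])),
           sprintf("CMP.%02d", seq_len(SMV_PANEL_SIZES[["complement"]])),
           sprintf("PLT.%02d", seq_len(SMV_PANEL_SIZES[["platelet"]])),
           sprintf("NOISE.%04d", seq_len(n_analytes - need)))
  role <- c(rep("true_marker", n_true),
            rep("confounded_marker", n_confounded),
            rep("smv_cell", SMV_PANEL_SIZES[["cell_contamination"]]),
            rep("smv_complement", SMV_PANEL_SIZES[["complement"]]),
            rep("smv_platelet", SMV_PANEL_SIZES[["platelet"]]),
            rep("noise", n_analytes - need))

  menu <- data.frame(analyte_id = ids, role = role,
                     direction = "none",
                     disease_fold_ad = 1, disease_fold_sq = 1,
                     lysis_loading = 0,
                     base_log2_mean = rnorm(n_analytes, 10, 1.5),
                     biological_sd_log2 = runif(n_analytes, 0.35, 0.65),
                     expression_prob = 1,
                     benign_fold = 1,
                     stringsAsFactors = FALSE)

  it <- which(menu$role == "true_marker")
  menu$direction[it] <- dir_true
  is_up <- dir_true == "up"
  menu$disease_fold_ad[it] <- ifelse(is_up, fold_ad, 1 / fold_ad)
  menu$disease_fold_sq[it] <- ifelse(is_up, fold_sq, 1 / fold_sq)
  menu$expression_prob[it] <- expression_prob
  # host-response markers are partially mimicked by inflammatory nodules
  inflam <- if (n_true <= 7L) it[ids_true %in% c("SERPINA3", "C9", "CRP")]
            else it[is_up][seq_along(it[is_up]) %% 2 == 0]
  menu$benign_fold[inflam] <- benign_fold

  ic <- which(menu$role == "confounded_marker")
  menu$lysis_loading[ic] <- confounded_loading
  if (confounded_fold_ad != 1 || confounded_fold_sq != 1) {
    menu$direction[ic] <- if (confounded_fold_ad >= 1) "up" else "down"
    menu$disease_fold_ad[ic] <- confounded_fold_ad
    menu$disease_fold_sq[ic] <- confounded_fold_sq
  }

  ip <- grepl("^smv_", menu$role)
  menu$lysis_loading[ip] <- runif(sum(ip), 0.7, 1.2)

  class(menu) <- c("analyte_menu", "data.frame")
  menu
}

#' Extract the SMV panel membership implied by an analyte menu
#'
#' @param menu an `analyte_menu`.
#' @param matrix_type `"serum"` or `"plasma"`; for serum the platelet panel
#'   is carried but excluded from scoring (platelets are consumed by
#'   clotting, so platelet-release signatures are uninformative in serum).
#' @return An `smv_panel_set`: list with `panels` (named list of analyte id
#'   vectors) and `matrix_type`.
#' @export
menu_smv_panels <- function(menu, matrix_type = c("serum", "plasma")) {
  matrix_type <- match.arg(matrix_type)
  smv_panel_set(
    panels = list(
      cell_contamination = menu$analyte_id[menu$role == "smv_cell"],
      complement         = menu$analyte_id[menu$role == "smv_complement"],
      platelet           = menu$analyte_id[menu$role == "smv_platelet"]),
    matrix_type = matrix_type)
}
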