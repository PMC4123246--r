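make_panels <- function(menu) menu_smv_panels(menu)

test_that("panel sets enforce the 30/4/16 structure and serum rule", {
  menu <- generate_analyte_menu(120, seed = 1)
  ps <- make_panels(menu)
  expect_s3_class(ps, "smv_panel_set")
  expect_error(smv_panel_set(list(cell_contamination = "a", complement = "b",
                                  platelet = "c")), "30 analytes")
  serum <- smvdiscover:::applicable_panels(ps)
  expect_setequal(serum, c("cell_contamination", "complement"))
  plasma <- menu_smv_panels(menu, matrix_type = "plasma")
  expect_true("platelet" %in% smvdiscover:::applicable_panels(plasma))
})

test_that("panel membership files round-trip", {
  menu <- generate_analyte_menu(120, seed = 1)
  ps <- make_panels(menu)
  path <- file.path(withr::local_tempdir(), "panels.csv")
  write_smv_panels(ps, path)
  back <- read_smv_panels(path)
  expect_equal(back$panels, ps$panels)
})

test_that("a sample at the reference medians scores zero on every panel", {
  menu <- generate_analyte_menu(120, seed = 2)
  s <- sim_cohort(seed = 2, design = small_design(2))
  ref_med <- apply(log2(s$matrix), 2, median)
  m <- rbind(s$matrix, REFSAMPLE = 2^ref_med)
  qa <- compute_smv_scores(m, s$panels, reference_barcodes = rownames(s$matrix))
  row <- qa$scores[qa$scores$barcode == "REFSAMPLE", ]
  expect_equal(row$cell_contamination, 0)
  expect_equal(row$complement, 0)
})

test_that("a uniform 2-fold panel elevation at MAD 0.5 scores exactly 2", {
  # reference log2 values alternate 10 +/- d with d chosen so mad() = 0.5
  menu <- generate_analyte_menu(120, seed = 3)
  d <- 0.5 / 1.4826
  n_ref <- 40
  base_log2 <- matrix(rep(c(10 - d, 10 + d), length.out = n_ref * 120),
                      nrow = n_ref, byrow = FALSE)
  m <- 2^base_log2
  rownames(m) <- sprintf("R%02d", seq_len(n_ref))
  colnames(m) <- menu$analyte_id
  elevated <- 2^(rep(10, 120) + ifelse(menu$role == "smv_cell", 1, 0))
  m <- rbind(m, ELEV = elevated)
  qa <- compute_smv_scores(m, make_panels(menu),
                           reference_barcodes = sprintf("R%02d", seq_len(n_ref)))
  expect_equal(qa$scores$cell_contamination[qa$scores$barcode == "ELEV"], 2)
  expect_equal(qa$scores$complement[qa$scores$barcode == "ELEV"], 0)
})

test_that("scores are invariant to per-sample scaling absorbed by normalization", {
  s <- sim_cohort(seed = 4, design = small_design(4))
  doubled <- s$matrix
  doubled[3, ] <- doubled[3, ] * 2
  qa1 <- compute_smv_scores(median_normalize(s$matrix)$matrix, s$panels)
  qa2 <- compute_smv_scores(median_normalize(doubled)$matrix, s$panels)
  expect_equal(qa1$scores, qa2$scores)
})

test_that("score computation validates its inputs", {
  s <- sim_cohort(seed = 5, design = small_design(5))
  no_panel <- setdiff(colnames(s$matrix), s$panels$panels$cell_contamination[1])
  expect_error(compute_smv_scores(s$matrix[, no_panel], s$panels), "missing")
  expect_error(compute_smv_scores(s$matrix[1:10, ], s$panels), ">= 20 reference")
  flat <- s$matrix
  flat[, s$panels$panels$complement[1]] <- 100
  expect_error(compute_smv_scores(flat, s$panels), "zero reference MAD")
})

test_that("quality classification follows the cutoff rule", {
  s <- sim_cohort(seed = 6, design = small_design(6))
  qa <- compute_smv_scores(median_normalize(s$matrix)$matrix, s$panels)
  all_high <- classify_quality(qa, Inf)
  expect_true(all(all_high$scores$category == "high"))
  expect_equal(all_high$scores$composite,
               pmax(all_high$scores$cell_contamination,
                    all_high$scores$complement))
  # category = high iff every applicable panel score under its cutoff
  fixed <- classify_quality(qa, c(cell_contamination = 1, complement = 0.5))
  expect_equal(fixed$scores$category == "high",
               fixed$scores$cell_contamination < 1 &
                 fixed$scores$complement < 0.5)
  expect_error(classify_quality(qa, "empirical:1.2"), "in \\(0, 1\\)")
})

test_that("empirical cutoffs reproduce the requested quality fraction", {
  for (seed in 1:3) {
    s <- sim_cohort(seed = seed, design = small_design(seed))
    qa <- compute_smv_scores(median_normalize(s$matrix)$matrix, s$panels)
    cl <- classify_quality(qa, "empirical:0.8")
    n <- nrow(cl$scores)
    n_high <- sum(cl$scores$category == "high")
    expect_true(n_high %in% c(floor(0.8 * n), ceiling(0.8 * n)))
  }
})

test_that("heavily contaminated samples are flagged with high sensitivity", {
  # plant severe contamination (3 log2 on panel proteins) in 20% of samples
  s <- sim_cohort(seed = 7, design = small_design(7))
  n <- nrow(s$matrix)
  set.seed(7)
  bad <- sample(rownames(s$matrix), round(0.2 * n))
  panel_an <- unlist(s$panels$panels[c("cell_contamination", "complement")])
  m <- s$matrix
  m[bad, panel_an] <- m[bad, panel_an] * 2^3
  qa <- classify_quality(compute_smv_scores(m, s$panels), 2)
  sens <- mean(qa$scores$category[qa$scores$barcode %in% bad] == "low")
  expect_gte(sens, 0.9)
})

test_that("site consistency reports planted site shifts and bias", {
  menu <- generate_analyte_menu(120, seed = 8)
  counts <- data.frame(site = rep(c("A", "B", "C"), each = 2),
                       group = rep(c("case", "control"), 3),
                       histology = rep(c("AD", "none"), 3),
                       stage = rep(c("II", "none"), 3),
                       control_subtype = rep(c("none", "smoker"), 3),
                       n = 100)
  design <- cohort_design(counts,
                          site_contamination_scale = c(A = 0.2, B = 1.6, C = 0.2),
                          casecontrol_bias = c(A = 0, B = 0, C = 1.5),
                          seed = 8)
  s <- simulate_cohort(menu, design)
  norm <- median_normalize(s$matrix, exclude = unlist(menu_smv_panels(menu)$panels))
  qa <- classify_quality(compute_smv_scores(norm$matrix, menu_smv_panels(menu)),
                         "empirical:0.8")
  decoy <- menu$analyte_id[menu$role == "confounded_marker"][1]
  truem <- menu$analyte_id[menu$role == "true_marker"][1]
  rpt <- site_consistency(norm$matrix, s$annotations, c(decoy, truem),
                          assessment = qa)
  folds <- rpt$analyte_folds
  expect_gt(folds$max_site_fold[folds$analyte_id == decoy], 2)
  expect_lt(folds$max_site_fold[folds$analyte_id == truem], 1.5)
  expect_true(all(folds$max_site_fold >= 1))
  bias <- rpt$site_bias
  expect_lt(bias$p_value[bias$site == "C"], 0.01)
  expect_gt(min(bias$p_value[bias$site %in% c("A", "B")]), 0.01)

  # a site with too few controls is dropped with a warning
  ann2 <- s$annotations
  drop <- ann2$barcode[ann2$site == "A" & ann2$group == "control"][1:97]
  keep <- setdiff(ann2$barcode, drop)
  expect_warning(
    site_consistency(norm$matrix[keep, ], ann2[ann2$barcode %in% keep, ],
                     decoy), "excluded")
  one_site <- ann2$barcode[ann2$site == "B"]
  expect_error(
    suppressWarnings(site_consistency(norm$matrix[one_site, ],
                                      ann2[ann2$barcode %in% one_site, ], decoy)),
    ">= 2 sites")
})
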