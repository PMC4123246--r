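test_that("analyte menu has the full SMV structure and requested roles", {
  menu <- generate_analyte_menu(1033, n_true = 7, n_confounded = 3, seed = 1)
  counts <- table(menu$role)
  expect_equal(unname(counts[["smv_cell"]]), 30)
  expect_equal(unname(counts[["smv_complement"]]), 4)
  expect_equal(unname(counts[["smv_platelet"]]), 16)
  expect_equal(unname(counts[["true_marker"]]), 7)
  expect_equal(unname(counts[["confounded_marker"]]), 3)
  expect_equal(unname(counts[["noise"]]), 1033 - 7 - 3 - 50)
  expect_false(anyDuplicated(menu$analyte_id) > 0)
})

test_that("menu generation is deterministic and enforces sizing", {
  m1 <- generate_analyte_menu(120, seed = 1)
  m2 <- generate_analyte_menu(120, seed = 1)
  expect_identical(m1, m2)
  expect_false(identical(m1, generate_analyte_menu(120, seed = 2)))
  err <- tryCatch(generate_analyte_menu(55, n_true = 7, n_confounded = 3),
                  error = identity)
  expect_s3_class(err, "smv_validation_error")
  expect_match(conditionMessage(err), "5 short")
})

test_that("menu invariants hold: loadings, directions, SQ >= AD effects", {
  menu <- generate_analyte_menu(200, n_true = 12, n_confounded = 3, seed = 3)
  expect_true(all(menu$lysis_loading[menu$role == "true_marker"] == 0))
  expect_true(all(menu$direction[grepl("^smv_", menu$role)] == "none"))
  expect_true(all(menu$lysis_loading[grepl("^smv_", menu$role)] > 0))
  tm <- menu[menu$role == "true_marker", ]
  expect_true(all(abs(log2(tm$disease_fold_sq)) >= abs(log2(tm$disease_fold_ad))))
  up <- tm[tm$direction == "up", ]
  dn <- tm[tm$direction == "down", ]
  expect_true(all(up$disease_fold_sq >= up$disease_fold_ad))
  expect_true(all(dn$disease_fold_sq <= dn$disease_fold_ad))
})

test_that("a menu without planted markers is SMV + noise only", {
  menu <- generate_analyte_menu(120, n_true = 0, n_confounded = 0, seed = 1)
  expect_setequal(unique(menu$role),
                  c("smv_cell", "smv_complement", "smv_platelet", "noise"))
})

test_that("cohort simulation is deterministic and strictly positive", {
  s <- sim_cohort(seed = 5, design = small_design(5))
  s2 <- sim_cohort(seed = 5, design = small_design(5))
  expect_identical(s$matrix, s2$matrix)
  expect_identical(s$annotations, s2$annotations)
  expect_true(all(s$matrix > 0))
  expect_false(anyDuplicated(s$annotations$barcode) > 0)
  expect_true(all(s$annotations$latent_contamination >= 0))
  # histology/stage are none exactly for controls
  ctrl <- s$annotations$group == "control"
  expect_true(all(s$annotations$histology[ctrl] == "none"))
  expect_true(all(s$annotations$stage[!ctrl] %in% c("I", "II", "III", "IV")))
})

test_that("empty or invalid designs are rejected", {
  counts <- data.frame(site = "A", group = "case", histology = "AD",
                       stage = "I", control_subtype = "none", n = 0)
  expect_error(cohort_design(counts, c(A = 1), c(A = 0)), "empty")
  counts$n <- 5
  expect_error(cohort_design(counts, c(A = 1), c(A = 0), assay_cv = 1.5), "assay_cv")
  counts$stage <- "V"
  expect_error(cohort_design(counts, c(A = 1), c(A = 0)), "stage")
})

test_that("mean planted level is monotone in stage within histology", {
  # fully penetrant markers so the stage gradient is visible in group means
  menu <- generate_analyte_menu(120, seed = 2, fold_ad = 1.6, fold_sq = 2.2,
                                expression_prob = 1)
  counts <- expand.grid(site = c("A", "B"), group = "case", histology = "AD",
                        stage = c("I", "II", "III", "IV"),
                        control_subtype = "none", stringsAsFactors = FALSE)
  counts$n <- 50
  counts <- rbind(counts,
                  data.frame(site = c("A", "B"), group = "control",
                             histology = "none", stage = "none",
                             control_subtype = "smoker", n = 50))
  design <- cohort_design(counts, c(A = 0.1, B = 0.1), c(A = 0, B = 0), seed = 2)
  s <- simulate_cohort(menu, design)
  up <- menu$analyte_id[menu$role == "true_marker" & menu$direction == "up"][1]
  lx <- log2(s$matrix[, up])
  means <- vapply(c("none", "I", "II", "III", "IV"), function(st)
    mean(lx[s$annotations$stage == st]), numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("per-marker case/control AUC matches the closed-form normal model", {
  # single histology and stage so the two-normal closed form applies exactly
  menu <- generate_analyte_menu(120, seed = 7, fold_ad = 1.6, fold_sq = 2.2,
                                expression_prob = 1)
  counts <- data.frame(site = c("A", "A"), group = c("case", "control"),
                       histology = c("AD", "none"), stage = c("I", "none"),
                       control_subtype = c("none", "smoker"), n = 200)
  design <- cohort_design(counts, c(A = 1e-4), c(A = 0),
                          assay_cv = 0.05, seed = 7)
  s <- simulate_cohort(menu, design)
  grp <- s$annotations$group
  asd <- sqrt(log(1 + 0.05^2)) / log(2)
  for (i in which(menu$role == "true_marker")) {
    lx <- log2(s$matrix[, menu$analyte_id[i]])
    emp <- roc_auc(lx[grp == "case"], lx[grp == "control"])
    delta <- log2(menu$disease_fold_ad[i])  # stage I factor = 1; sign carries direction
    sd_tot <- sqrt(menu$biological_sd_log2[i]^2 + asd^2)
    expected <- normal_model_auc(delta, sd_tot)
    expect_lt(abs(emp - expected), 0.05)
  }
})

test_that("true markers are uncorrelated with latent contamination", {
  s <- sim_cohort(seed = 3, design = small_design(3, frac = 1))
  truth <- s$menu$analyte_id[s$menu$role == "true_marker"]
  ctrl <- s$annotations$group == "control"
  for (a in truth) {
    r <- cor(log2(s$matrix[ctrl, a]), s$annotations$latent_contamination[ctrl])
    expect_lt(abs(r), 0.2)
  }
})

test_that("cohort files round-trip exactly", {
  stem <- file.path(withr::local_tempdir(), "toy")
  s <- sim_cohort(seed = 1, design = small_design(1, frac = 0.2))
  write_cohort(s$matrix, s$annotations, stem)
  back <- read_cohort(stem)
  expect_equal(back$matrix, s$matrix, tolerance = 1e-12)
  expect_identical(colnames(back$matrix), colnames(s$matrix))
  expect_identical(rownames(back$matrix), rownames(s$matrix))
  expect_equal(back$annotations$barcode, s$annotations$barcode)
  expect_equal(back$annotations$latent_contamination,
               s$annotations$latent_contamination, tolerance = 1e-6)
})

test_that("cohort readers enforce the container invariants", {
  dir <- withr::local_tempdir()
  m <- toy_matrix(matrix(c(1, 2, 3, 4, 5, 6), nrow = 2, byrow = TRUE))
  ann <- data.frame(barcode = rownames(m))
  write_cohort(m, ann, file.path(dir, "ok"))

  # zero RFU rejected with the offending cell named
  bad <- m; bad["S01", "A02"] <- 0
  expect_error(validate_rfu(bad), "S01.*A02")
  rfu_path <- file.path(dir, "zero_rfu.csv")
  df <- data.frame(barcode = rownames(m), bad, check.names = FALSE)
  write.csv(df, rfu_path, row.names = FALSE)
  file.copy(file.path(dir, "ok_meta.csv"), file.path(dir, "zero_meta.csv"))
  err <- tryCatch(read_cohort(file.path(dir, "zero")), error = identity)
  expect_s3_class(err, "smv_validation_error")

  # duplicated analyte column named in the error
  lines <- readLines(file.path(dir, "ok_rfu.csv"))
  lines[1] <- "barcode,A01,A01,A03"
  writeLines(lines, file.path(dir, "dup_rfu.csv"))
  file.copy(file.path(dir, "ok_meta.csv"), file.path(dir, "dup_meta.csv"))
  expect_error(read_cohort(file.path(dir, "dup")), "A01")

  # duplicated barcode rejected
  lines <- readLines(file.path(dir, "ok_rfu.csv"))
  lines[3] <- sub("^S02", "S01", lines[3])
  writeLines(lines, file.path(dir, "dupbc_rfu.csv"))
  file.copy(file.path(dir, "ok_meta.csv"), file.path(dir, "dupbc_meta.csv"))
  expect_error(read_cohort(file.path(dir, "dupbc")), "S01")
})
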