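# Shared fixture builders. All fixtures are generated in code.

# A tiny labelled RFU matrix.
toy_matrix <- function(values, barcodes = NULL, analytes = NULL) {
  m <- as.matrix(values)
  rownames(m) <- barcodes %||% sprintf("S%02d", seq_len(nrow(m)))
  colnames(m) <- analytes %||% sprintf("A%02d", seq_len(ncol(m)))
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Default training design scaled down for fast module tests.
small_design <- function(seed = 1, confounded = FALSE, frac = 0.5) {
  d <- default_training_design(seed = seed, confounded = confounded)
  d$counts$n <- ceiling(d$counts$n * frac)
  d
}

# A simulated cohort plus its menu and panel set, in one call.
sim_cohort <- function(seed = 1, n_analytes = 120, confounded = FALSE,
                       design = NULL, ...) {
  menu <- generate_analyte_menu(n_analytes, seed = seed, ...)
  design <- design %||% default_training_design(seed = seed, confounded = confounded)
  cohort <- simulate_cohort(menu, design)
  list(menu = menu, design = design, matrix = cohort$matrix,
       annotations = cohort$annotations,
       panels = menu_smv_panels(menu))
}
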