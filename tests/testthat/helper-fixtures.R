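# Small hand-built fixtures used across test files.

options(tcx.verbose = FALSE)

# A tiny study from explicit per-gene signal rows (one age, one time point,
# 3 control + 3 treated samples) with all-Present calls unless given.
tiny_study <- function(signal_rows, calls_rows = NULL) {
  genes <- names(signal_rows)
  sig <- do.call(rbind, signal_rows)
  colnames(sig) <- c(paste0("PBS_r", 1:3), paste0("KA_r", 1:3))
  rownames(sig) <- genes
  calls <- if (is.null(calls_rows)) {
    matrix("P", nrow(sig), ncol(sig), dimnames = dimnames(sig))
  } else {
    m <- do.call(rbind, calls_rows)
    dimnames(m) <- dimnames(sig)
    m
  }
  design <- data.frame(sample_id = colnames(sig), age = "P30",
                       treatment = rep(c("PBS", "KA"), each = 3),
                       time_h = 24, replicate = rep(1:3, 2),
                       stringsAsFactors = FALSE)
  expression_study(sig, calls, design, mode = "rat")
}

tiny_control <- function(study) select_samples(study, treatment = "PBS")
tiny_treated <- function(study) select_samples(study, treatment = "KA")

# A minimal composite table from a named list gene -> description vector.
composite_of <- function(desc_list) {
  build_composite(list(data.frame(
    symbol = rep(names(desc_list), lengths(desc_list)),
    description = unlist(desc_list, use.names = FALSE),
    stringsAsFactors = FALSE)))
}

# Single-contrast design used for calibration/power studies.
flat_design <- function(n_genes) {
  design_spec(age_groups = "P30", treatments = c("PBS", "KA"),
              time_points_h = 24, replicates_per_cell = 3, n_genes = n_genes)
}

no_effects <- function(...) {
  effect_spec(effects = data.frame(gene = character(), age = character(),
                                   time_h = numeric(), lfc = numeric()), ...)
}
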