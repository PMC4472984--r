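# Shared builders for in-code fixtures.

tiny_design <- function(...) {
  QpcrDesign(reference_gene = "IF4a",
             control_treatment = "water", stress_treatment = "dehydration",
             tolerant_cultivar = "TOL", sensitive_cultivar = "SEN",
             timepoints = c(2, 5), ...)
}

# long-format records for a full factorial with constant reference Cq and
# per-gene target Cq supplied as a named list of functions(cell) or numbers
tiny_records <- function(genes = c("gA", "gB"),
                         cultivars = "TOL", tissues = "root",
                         treatments = c("water", "dehydration"),
                         timepoints = c(2, 5), reps = 3,
                         ref_cq = 20, target_cq = 24) {
  grid <- expand.grid(cultivar = cultivars, tissue = tissues,
                      treatment = treatments, timepoint_h = timepoints,
                      bio_replicate = seq_len(reps),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  recs <- do.call(rbind, lapply(c(genes, "IF4a"), function(g) {
    df <- grid
    df$gene_id <- g
    df$cq <- if (g == "IF4a") ref_cq else target_cq
    df
  }))
  recs[, c("gene_id", "cultivar", "tissue", "treatment", "timepoint_h",
           "bio_replicate", "cq")]
}

# scenario with a single programmed effect, handy for call checks
effect_scenario <- function(lfc, n_genes = 1, noise_sd = 0,
                            timepoints = c(2, 5), cultivars = "TOL",
                            baseline = 5, n_replicates = 3L) {
  CqScenario(genes = sprintf("g%03d", seq_len(n_genes)),
             cultivars = cultivars, tissues = "root",
             treatments = c("water", "dehydration"),
             timepoints = timepoints, n_replicates = n_replicates,
             baseline_dct = baseline, true_log2fc = lfc,
             noise_sd = noise_sd)
}

expect_setequal_sorted <- function(object, expected) {
  expect_identical(sort(object), sort(expected))
}
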