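#!/usr/bin/env Rscript
# Generate the synthetic GWAS panels used by the downstream analyses: nine
# exposures (mirroring the nine clonal-hematopoiesis instrument sets, with
# their published instrument counts) and five stroke-like outcomes built
# over the union of the exposures' SNPs.  Only the TET2-like exposure is
# causal for the outcomes (theta = 0.25); the others are null, so the grid
# has a known signal to find and known negatives to leave alone.  Panels are
# written as standard summary-statistic TSVs under results/sim/.

suppressPackageStartupMessages(library(strokemr))

seed <- 20260930L
out_dir <- "results/sim"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

# Instrument counts per exposure follow the study's nine CH instrument sets;
# each exposure lives in its own SNP namespace (no shared instruments).
exposure_counts <- c(ALL = 95, ASXL1 = 11, DNMT3A = 22, GNB1 = 8, JAK2 = 7,
                     PPM1D = 13, SF3B1 = 4, SRSF2 = 4, TET2 = 17)
outcome_names <- c("overall_stroke", "ischemic_stroke", "TIA", "SVS", "LAS")
n_snps_each <- 600

# Shared with 02_mr_grid.R: per-exposure generator config and SNP relabeling.
exposure_cfg <- function(name, i) {
  sim_config(n_snps_total = n_snps_each,
             n_instruments = exposure_counts[[name]],
             theta = if (name == "TET2") 0.25 else 0,
             seed = seed + i)
}
relabel <- function(ids, name) paste0(name, "_", ids)

cat("Simulating", length(exposure_counts), "exposures and",
    length(outcome_names), "outcomes (seed", seed, ")\n")

sims <- list()
for (i in seq_along(exposure_counts)) {
  name <- names(exposure_counts)[i]
  sim <- simulate_exposure(exposure_cfg(name, i))
  sim$stats$records$snp_id <- relabel(sim$stats$records$snp_id, name)
  sim$stats$trait_name <- name
  sim$truth$snp_id <- relabel(sim$truth$snp_id, name)
  sims[[name]] <- sim
  write_sumstats(sim$stats, file.path(out_dir, paste0("exposure_", name, ".tsv")))
  write.table(sim$truth, file.path(out_dir, paste0("truth_", name, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cat(sprintf("  %-8s %3d instruments planted (theta = %.2f), %d SNPs\n",
              name, exposure_counts[[name]],
              if (name == "TET2") 0.25 else 0, n_snps(sim$stats)))
}

# Each outcome concatenates per-exposure outcome slices simulated from each
# exposure's own ground truth, so instrument SNPs stay disjoint.
for (j in seq_along(outcome_names)) {
  slices <- lapply(names(exposure_counts), function(name) {
    i <- match(name, names(exposure_counts))
    cfg <- exposure_cfg(name, i)
    cfg$seed <- cfg$seed + 100L * j        # independent outcome panels per j
    cfg$outcome_n <- 3e5 + j * 1e4
    truth <- sims[[name]]$truth
    attr(truth, "alleles") <- attr(sims[[name]]$truth, "alleles")
    simulate_outcome(truth, cfg)$records
  })
  rec <- do.call(rbind, slices)
  out <- sumstats(rec, outcome_names[j], "case_control", "simulated")
  write_sumstats(out, file.path(out_dir, paste0("outcome_", outcome_names[j], ".tsv")))
}
cat("Wrote", length(exposure_counts) + length(outcome_names),
    "summary-statistic tables to", out_dir, "\n")
cat("Ground truth: causal effect 0.25 (log-odds) from the TET2-like exposure;\n")
cat("all other exposures are null for these outcomes.\n")
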