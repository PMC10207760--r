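#!/usr/bin/env Rscript

# Step 1: generate the synthetic study data.
#
# Builds (i) a two-exposure blood-pressure scenario — SBP and DBP summary
# statistics on a shared 450-variant panel (757,601-person exposure sample,
# SD 21.5 / 11.4 mmHg, ~1.6%/1.7% variance explained) with planted causal
# effects on residual age at onset (0.0041 and 0.0138 years per mmHg) in a
# 9,064-person outcome sample — and (ii) a drug-target scenario with cis
# regions for three antihypertensive classes (1 ACEI, 8 BB, 60 CCB proxy
# variants; the CCB region carries 0.022 years/mmHg, i.e. about -0.22 years
# per 10 mmHg SBP decrease). Writes everything as the TSV/BED dialects the
# readers consume.

suppressPackageStartupMessages(library(mrpipe))
args <- commandArgs(trailingOnly = TRUE)
seed <- as.integer(if (length(args) >= 2 && args[1] == "--seed") args[2] else "1")
data_dir <- "results/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

message("Simulating blood-pressure scenario (seed ", seed, ") ...")
bp <- generate_multi_exposure(
  scenario_config(n_snps = 450, trait_sd = c(21.5, 11.4),
                  r2_target = c(0.0159, 0.0171)),
  beta_causal = c(SBP = 0.0041, DBP = 0.0138), rho = 0.5, seed = seed)
write_summary_stats(bp$exposures$SBP, file.path(data_dir, "sbp.tsv"))
write_summary_stats(bp$exposures$DBP, file.path(data_dir, "dbp.tsv"))
write_summary_stats(bp$outcome, file.path(data_dir, "outcome_bp.tsv"))
write_ld_reference(bp$ld, file.path(data_dir, "bp_ld_pairs.tsv"),
                   file.path(data_dir, "bp_ld_variants.tsv"))
conf <- generate_confounder_table(bp$exposures$SBP$snp, seed = seed + 1L)
write.table(conf, file.path(data_dir, "confounders.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

message("Simulating drug-target scenario ...")
drug <- generate_two_sample(
  scenario_config(
    n_snps = 500,
    gene_regions = list(
      ACEI = list(gene = "ACE", n_snps = 1, within_r2 = 0.3),
      BB = list(gene = "ADRB1", n_snps = 8, within_r2 = c(0, 0.35)),
      CCB = list(gene = "CACNA1C", n_snps = 60, within_r2 = c(0, 0.35),
                 beta_causal = 0.022))),
  synthetic_truth(beta_causal = 0.0041, seed = seed + 3L))
write_scenario(drug, file.path(data_dir, "drug"))

message("Done. Inputs written under ", data_dir, ":")
for (f in list.files(data_dir, recursive = TRUE)) message("  ", f)
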