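#!/usr/bin/env Rscript

# Step 1 - simulate the fractionation experiment.
#
# Generates the ground-truth proteome and every input table the analysis
# consumes: peptide-level intensities for the mitochondrial, chloroplast
# and whole-cell fractions (3 replicates each), TargetP-style prediction
# tables for three transcriptome variants, reference-mitoproteome
# ortholog tables, and the truth table used later for evaluation.

suppressPackageStartupMessages(library(mitosieve))

out <- "results/synthetic"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- simulation_config(n_proteins = 2000, seed = 42)
yaml::write_yaml(list(simulate = unclass(cfg)), file.path(out, "config.yaml"))

truth <- generate_proteome(cfg)
write_tsv_table(truth, file.path(out, "truth.tsv"))
write_proteome_fasta(truth, file.path(out, "proteome.fasta"))

obs <- simulate_observations(truth, cfg)
write_observations(obs, file.path(out, "observations.tsv"))

targeting <- simulate_targeting_tables(truth, cfg)
for (tx in names(targeting)) {
  write_tsv_table(targeting[[tx]], file.path(out, sprintf("targetp_%s.tsv", tx)))
}

orthologs <- simulate_ortholog_tables(truth, cfg)
write_tsv_table(orthologs, file.path(out, "orthologs.tsv"))

cat(sprintf(
  "simulated %d proteins (%d mito, %d chloroplast, %d cytosol, %d dual)\n",
  nrow(truth),
  sum(truth$localization == "mito"), sum(truth$localization == "chloroplast"),
  sum(truth$localization == "cytosol"), sum(truth$localization == "dual")
))
cat(sprintf(
  "%d peptide observations across 9 samples; %d ortholog links\n",
  nrow(obs), nrow(orthologs)
))
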