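#!/usr/bin/env Rscript

# Step 2 - protein inference.
#
# Collapses I/L, filters short peptides, forms protein groups by
# peptide-set subsumption, counts unique vs razor peptides, and applies
# the 1% target-decoy FDR to the identification scores.

suppressPackageStartupMessages(library(mitosieve))

src <- "results/synthetic"
out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- yaml::read_yaml(file.path(src, "config.yaml"))$simulate
obs <- read_observations(file.path(src, "observations.tsv"))

matches <- peptide_matches(obs, min_length = cfg$min_peptide_length)
groups <- group_proteins(matches)
uniq <- count_unique_peptides(groups, matches)

write_peptides_table(matches, file.path(out, "peptides.tsv"))

observed <- sort(unique(unlist(matches$proteins)))
scores <- simulate_decoy_scores(
  length(observed), length(observed),
  separation = cfg$id_score_separation, seed = cfg$seed + 4
)
scores$id[!scores$is_decoy] <- observed
fdr <- decoy_fdr_threshold(scores, level = 0.01)
writeLines(sort(fdr$accepted$id), file.path(out, "candidates.txt"))

cat(sprintf(
  "%d canonical peptides -> %d protein groups (%d multi-unique, %d single-unique, %d none)\n",
  nrow(matches), nrow(groups),
  uniq$partition["multi"], uniq$partition["single"], uniq$partition["none"]
))
cat(sprintf(
  "FDR 0.01: threshold %.3f, %d candidates accepted, %d decoys (estimated FDR %.4f)\n",
  fdr$threshold, fdr$accepted_targets, fdr$accepted_decoys, fdr$fdr
))
write_tsv_table(uniq$counts, file.path(out, "unique_peptides.tsv"))
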