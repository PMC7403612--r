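#!/usr/bin/env Rscript

# Step 3 - quantification.
#
# Sums unique-peptide intensities per group and sample, computes Mt/Cp
# and Mt/WC enrichment ratios with confidence bins, Welch volcano
# statistics (Mt vs Cp on log10 intensities), and molecular weights.

suppressPackageStartupMessages(library(mitosieve))

src <- "results/synthetic"
out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- yaml::read_yaml(file.path(src, "config.yaml"))$simulate
obs <- read_observations(file.path(src, "observations.tsv"))
truth <- read_tsv_table(file.path(src, "truth.tsv"))

matches <- peptide_matches(obs, min_length = cfg$min_peptide_length)
groups <- group_proteins(matches)
uniq <- count_unique_peptides(groups, matches)
ints <- aggregate_group_intensity(groups, matches)
enr <- enrichment_ratios(ints)

write_protein_groups_table(groups, uniq$counts, ints, file.path(out, "proteinGroups.tsv"))
write_tsv_table(enr, file.path(out, "enrichment.tsv"))

# volcano statistics per quantifiable group (log10, zeros -> missing)
mt_cols <- grep("^mt_", names(ints), value = TRUE)
cp_cols <- grep("^cp_", names(ints), value = TRUE)
volcano <- do.call(rbind, lapply(seq_len(nrow(ints)), function(i) {
  x <- log10(pmax(as.numeric(ints[i, mt_cols]), 1))
  y <- log10(pmax(as.numeric(ints[i, cp_cols]), 1))
  s <- volcano_stats(x, y)
  data.frame(group_id = ints$group_id[i], lfc = s$lfc, p_value = s$p_value)
}))
write_tsv_table(volcano, file.path(out, "volcano.tsv"))

# molecular weights of the leading proteins
mw <- round(molecular_weight(
  setNames(truth$sequence, truth$protein_id)[groups$leader]
), 2)
write_tsv_table(
  data.frame(group_id = groups$group_id, leader = groups$leader, mw_kda = mw),
  file.path(out, "molecular_weights.tsv")
)

cat(sprintf(
  "%d groups quantified; %d enriched (both ratios > 1); bins: %s\n",
  sum(ints$quantifiable), sum(enr$enriched),
  paste(names(table(enr$confidence_bin)), table(enr$confidence_bin),
    sep = "=", collapse = ", "
  )
))
cat(sprintf(
  "molecular weight range %.2f-%.2f kDa; %d (%d%%) below 50 kDa\n",
  max(mw), min(mw), sum(mw < 50), percent_round(sum(mw < 50), length(mw))
))
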