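#!/usr/bin/env Rscript

# Step 4 - evidence layers.
#
# Scores each FDR-accepted candidate on the three membership strategies:
# orthology against the reference mitoproteomes, fraction enrichment
# (from step 3), and the 2-of-3 methionine-start targeting consensus.

suppressPackageStartupMessages(library(mitosieve))

src <- "results/synthetic"
out <- "results/analysis"

cfg <- yaml::read_yaml(file.path(src, "config.yaml"))$simulate
truth <- read_tsv_table(file.path(src, "truth.tsv"))
obs <- read_observations(file.path(src, "observations.tsv"))
orthologs <- read_tsv_table(file.path(src, "orthologs.tsv"))
targeting <- lapply(
  setNames(nm = c("t1", "t2", "t3")),
  function(tx) read_targetp(file.path(src, sprintf("targetp_%s.tsv", tx)))
)
candidates <- readLines(file.path(out, "candidates.txt"))

matches <- peptide_matches(obs, min_length = cfg$min_peptide_length)
groups <- group_proteins(matches)
enr <- enrichment_ratios(aggregate_group_intensity(groups, matches))

orthology <- ortholog_membership(
  candidates, orthologs, reference_species_names(cfg$n_reference_proteomes)
)
consensus <- targeting_consensus(
  stack_targeting_tables(targeting),
  protein_ids = candidates, k = 3
)

cand_tbl <- truth[match(candidates, truth$protein_id), ]
profiles <- build_evidence_profiles(
  tibble::tibble(
    protein_id = candidates,
    predicted_mito = cand_tbl$predicted_mito,
    annotation_mito_function = cand_tbl$annotation_mito_function,
    annotation_clear_nonmito = cand_tbl$is_contaminant_annotation
  ),
  orthology, enr, consensus,
  groups = groups
)
write_tsv_table(profiles, file.path(out, "evidence_profiles.tsv"))

cat(sprintf(
  "of %d candidates: %d orthology members, %d enriched, %d targeting consensus\n",
  length(candidates), sum(profiles$ortholog_member),
  sum(profiles$enriched), sum(profiles$targeting_consensus)
))
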