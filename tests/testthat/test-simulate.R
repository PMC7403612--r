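# Synthetic-data generator: configuration, proteome, digest,
# observations, targeting, orthologs, decoys.

test_that("configuration validation rejects malformed parameters", {
  expect_error(
    simulation_config(localization_proportions = c(
      mito = 0.5, chloroplast = 0.5, cytosol = 0.5, dual = 0
    )),
    "sum to 1"
  )
  expect_error(simulation_config(missing_rate = 1.5), "\\[0, 1\\]")
  expect_error(simulation_config(enrichment_fold = 0), "enrichment_fold")
  expect_error(simulation_config(missed_cleavages = 3), "missed_cleavages")
})

test_that("proteome generation honours size, proportions and determinism", {
  cfg <- simulation_config(
    n_proteins = 100,
    localization_proportions = c(mito = 1, chloroplast = 0, cytosol = 0, dual = 0),
    seed = 1
  )
  truth <- generate_proteome(cfg)
  expect_equal(nrow(truth), 100)
  expect_true(all(truth$localization == "mito"))

  empty <- generate_proteome(simulation_config(n_proteins = 0))
  expect_equal(nrow(empty), 0)

  cfg2 <- simulation_config(n_proteins = 200, seed = 11)
  t1 <- generate_proteome(cfg2)
  t2 <- generate_proteome(cfg2)
  expect_identical(t1, t2)
  counts <- table(t1$localization)
  expect_equal(as.integer(counts[c("mito", "chloroplast", "cytosol", "dual")]),
    c(70, 50, 70, 10))
  expect_false(any(duplicated(t1$protein_id)))
  expect_true(all(nchar(t1$sequence) >= 50))
})

test_that("tryptic digest follows the K/R-not-before-P rule", {
  expect_equal(
    digest_tryptic("AAAAAKCCCCCC", min_length = 6),
    c("AAAAAK", "CCCCCC")
  )
  expect_equal(digest_tryptic("AAAKPAAA", min_length = 1), "AAAKPAAA")
  expect_equal(digest_tryptic("KKK", min_length = 6), character())
  expect_error(digest_tryptic("AAAB"), "alphabet")

  # missed cleavages join adjacent fragments
  mc1 <- digest_tryptic("AAAAAKCCCCCCKDDDDDD", min_length = 6, missed_cleavages = 1)
  expect_true(all(c(
    "AAAAAK", "CCCCCCK", "DDDDDD", "AAAAAKCCCCCCK", "CCCCCCKDDDDDD"
  ) %in% mc1))
})

test_that("digest concatenation restores the input on random sequences", {
  set.seed(101)
  for (i in 1:1000) {
    s <- random_aa_string(sample(10:120, 1))
    expect_identical(paste(digest_tryptic(s, min_length = 1), collapse = ""), s)
  }
})

test_that("zero-noise observations recover the configured fold exactly", {
  cfg <- simulation_config(
    n_proteins = 30, intensity_log_sd = 0, missing_rate = 0,
    detectability = 1, contaminant_rate = 0, seed = 5
  )
  truth <- generate_proteome(cfg)
  obs <- simulate_observations(truth, cfg)
  matches <- peptide_matches(obs)
  groups <- group_proteins(matches)
  enr <- enrichment_ratios(aggregate_group_intensity(groups, matches))
  lk <- setNames(rep(groups$group_id, groups$n_members), unlist(groups$members))
  mito <- truth$protein_id[truth$localization == "mito"]
  r <- enr$ratio_mt_cp[match(unique(lk[mito]), enr$group_id)]
  expect_equal(r, rep(cfg$enrichment_fold, length(r)), tolerance = 1e-12)
})

test_that("missing_rate = 1 yields an empty observation table", {
  cfg <- simulation_config(n_proteins = 10, missing_rate = 1, seed = 2)
  obs <- simulate_observations(generate_proteome(cfg), cfg)
  expect_equal(nrow(obs), 0)
})

test_that("observation generation is deterministic given the seed", {
  cfg <- simulation_config(n_proteins = 40, seed = 9)
  truth <- generate_proteome(cfg)
  expect_identical(
    simulate_observations(truth, cfg),
    simulate_observations(truth, cfg)
  )
  expect_identical(
    simulate_targeting_tables(truth, cfg),
    simulate_targeting_tables(truth, cfg)
  )
  expect_identical(
    simulate_ortholog_tables(truth, cfg),
    simulate_ortholog_tables(truth, cfg)
  )
})

test_that("mean log10 Mt/Cp of mito proteins matches the configured fold", {
  cfg <- simulation_config(
    n_proteins = 1000,
    localization_proportions = c(mito = 1, chloroplast = 0, cytosol = 0, dual = 0),
    seed = 17
  )
  truth <- generate_proteome(cfg)
  obs <- simulate_observations(truth, cfg)
  matches <- peptide_matches(obs)
  groups <- group_proteins(matches)
  enr <- enrichment_ratios(aggregate_group_intensity(groups, matches))
  lg <- enr$log10_mt_cp[is.finite(enr$log10_mt_cp)]
  se <- sd(lg) / sqrt(length(lg))
  expect_lt(abs(mean(lg) - log10(cfg$enrichment_fold)), 3 * se)
})

test_that("targeting tables react to truncation as specified", {
  base <- simulation_config(n_proteins = 60, seed = 3, targeting_fp_rate = 0)
  truth <- generate_proteome(base)
  signal <- truth$protein_id[truth$has_targeting_signal]

  none <- simulation_config(n_proteins = 60, seed = 3,
    truncation_prob = 0, targeting_fp_rate = 0)
  tabs <- simulate_targeting_tables(truth, none)
  for (tab in tabs) {
    expect_true(all(tab$loc[tab$name %in% signal] == "M"))
    expect_true(all(tab$start_met))
  }

  all_trunc <- simulation_config(n_proteins = 60, seed = 3, truncation_prob = 1)
  tabs <- simulate_targeting_tables(truth, all_trunc)
  for (tab in tabs) {
    expect_false(any(tab$loc == "M" & tab$start_met))
  }
})

test_that("ortholog tables honour coverage limits", {
  cfg1 <- simulation_config(n_proteins = 50, seed = 4,
    reference_coverage = 1, ortholog_fp_rate = 0)
  truth <- generate_proteome(cfg1)
  tab <- simulate_ortholog_tables(truth, cfg1)
  mito <- truth$protein_id[truth$localization %in% c("mito", "dual")]
  per_protein <- table(tab$protein_id[tab$protein_id %in% mito])
  expect_equal(length(per_protein), length(mito))
  expect_true(all(per_protein == cfg1$n_reference_proteomes))

  cfg0 <- simulation_config(n_proteins = 50, seed = 4,
    reference_coverage = 0, ortholog_fp_rate = 0)
  tab0 <- simulate_ortholog_tables(truth, cfg0)
  expect_equal(nrow(tab0), 0)
})

test_that("extreme score separation admits all targets and no decoys", {
  scored <- simulate_decoy_scores(200, 200, separation = 50, seed = 6)
  res <- decoy_fdr_threshold(scored, level = 0.01)
  expect_equal(res$accepted_targets, 200L)
  expect_equal(res$accepted_decoys, 0L)
  expect_equal(res$fdr, 0)
})
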