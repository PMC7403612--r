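# End-to-end driver: synthetic data -> inference -> quantification ->
# evidence -> integration -> reporting.

#' Run the full verification pipeline
#'
#' Generates (or loads) the inputs, runs identification (peptide
#' canonicalisation, subsumption grouping, target-decoy FDR),
#' quantification (unique-peptide intensities, enrichment ratios),
#' evidence (orthology, targeting consensus), integration (strategy
#' union, curation, assembly), and reporting (category summary,
#' molecular weights). With an `out_dir`, writes every artifact: truth
#' and observation TSVs, FASTA, peptides and proteinGroups tables,
#' per-protein decisions, the final proteome, a summary JSON and a
#' plain-text log. Deterministic given the config seed: re-running with
#' the same config yields byte-identical outputs.
#'
#' @param config A [simulation_config()], a list with a `simulate`
#'   section of [simulation_config()] arguments (plus optional `fdr`
#'   with `level`/`separation` and `integrate` with `rule`), or the path
#'   to a YAML file with those sections.
#' @param out_dir Optional output directory (created if needed).
#' @return List with every intermediate and final artifact: `truth`,
#'   `observations`, `matches`, `groups`, `unique_counts`, `partition`,
#'   `intensities`, `enrichment`, `fdr`, `profiles`, `unioned`,
#'   `decisions`, `final`, `summary`, `evaluation`, `categories`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- normalize_pipeline_config(config)
  sim <- cfg$simulate
  log_lines <- character()
  log_add <- function(...) {
    line <- paste0(...)
    log_lines <<- c(log_lines, line)
    message(line)
  }

  # -- synthetic inputs ------------------------------------------------
  truth <- generate_proteome(sim)
  observations <- simulate_observations(truth, sim)
  targeting <- simulate_targeting_tables(truth, sim)
  orthologs <- simulate_ortholog_tables(truth, sim)
  log_add(
    "simulated ", nrow(truth), " proteins, ",
    nrow(observations), " peptide observations"
  )

  # -- identification --------------------------------------------------
  matches <- peptide_matches(observations, sim$min_peptide_length)
  groups <- group_proteins(matches)
  uniq <- count_unique_peptides(groups, matches)
  observed_proteins <- sort(unique(unlist(matches$proteins, use.names = FALSE)))
  scores <- with_seed(sim$seed + 4L, tibble::tibble(
    id = c(observed_proteins, sprintf("REV__%s", observed_proteins)),
    score = c(
      stats::rnorm(length(observed_proteins), cfg$fdr$separation, 1),
      stats::rnorm(length(observed_proteins), 0, 1)
    ),
    is_decoy = rep(c(FALSE, TRUE), each = length(observed_proteins))
  ))
  fdr <- decoy_fdr_threshold(scores, level = cfg$fdr$level)
  candidates <- if (nrow(fdr$accepted) > 0) sort(fdr$accepted$id) else character()
  log_add(
    length(observed_proteins), " proteins observed; ",
    length(candidates), " candidates at FDR ", cfg$fdr$level,
    " (threshold ", signif(fdr$threshold, 4), ", ",
    fdr$accepted_decoys, " decoys)"
  )

  # -- quantification --------------------------------------------------
  intensities <- aggregate_group_intensity(groups, matches)
  # a fraction with no surviving observation still exists in the design:
  # fill its samples with zero intensity so ratios are defined
  for (fr in c("mt", "cp", "wc")) {
    for (r in seq_len(sim$n_replicates_per_fraction)) {
      col <- paste(fr, r, sep = "_")
      if (!col %in% names(intensities)) intensities[[col]] <- 0
    }
  }
  enrichment <- enrichment_ratios(intensities)

  # -- evidence --------------------------------------------------------
  cand_truth <- truth[truth$protein_id %in% candidates, , drop = FALSE]
  cand_tbl <- tibble::tibble(
    protein_id = cand_truth$protein_id,
    predicted_mito = cand_truth$predicted_mito,
    annotation_mito_function = cand_truth$annotation_mito_function,
    annotation_clear_nonmito = cand_truth$is_contaminant_annotation
  )
  orthology <- ortholog_membership(
    cand_tbl$protein_id, orthologs,
    reference_species_names(sim$n_reference_proteomes)
  )
  consensus <- targeting_consensus(
    stack_targeting_tables(targeting),
    protein_ids = cand_tbl$protein_id, k = 3
  )
  profiles <- build_evidence_profiles(
    cand_tbl, orthology, enrichment, consensus,
    groups = groups
  )

  # -- integration -----------------------------------------------------
  unioned <- strategy_union(profiles, rule = cfg$integrate$rule)
  decisions <- curate(unioned)
  assembled <- assemble(unioned, decisions)
  log_add(
    "union ", assembled$summary$union, "; removed ",
    assembled$summary$removed, "; reintegrated ",
    assembled$summary$reintegrated, "; final ", assembled$summary$final
  )

  # -- evaluation against ground truth ---------------------------------
  evaluation <- evaluate_recovery(assembled$final$id, truth)
  log_add(
    "recovery vs truth: recall ", round(evaluation$recall, 4),
    ", precision ", round(evaluation$precision, 4)
  )

  # -- reporting -------------------------------------------------------
  final_ids <- assembled$final$id
  member_tbl <- tibble::tibble(
    id = final_ids,
    category = stats::setNames(truth$category, truth$protein_id)[final_ids],
    ratio_mt_cp = stats::setNames(profiles$ratio_mt_cp, profiles$id)[final_ids],
    mw_kda = round(molecular_weight(
      stats::setNames(truth$sequence, truth$protein_id)[final_ids]
    ), 2)
  )
  categories <- category_summary(member_tbl)
  summary <- c(
    assembled$summary,
    list(
      observed_proteins = length(observed_proteins),
      fdr_threshold = fdr$threshold,
      fdr_accepted_decoys = fdr$accepted_decoys,
      groups_total = nrow(groups),
      groups_multi_unique = unname(uniq$partition["multi"]),
      groups_single_unique = unname(uniq$partition["single"]),
      unknown_function = categories$n_unknown,
      unknown_function_percent = categories$unknown_percent,
      annotated = categories$n_annotated,
      recall = evaluation$recall,
      precision = evaluation$precision
    )
  )

  out <- list(
    truth = truth, observations = observations, targeting = targeting,
    orthologs = orthologs, matches = matches, groups = groups,
    unique_counts = uniq$counts, partition = uniq$partition,
    intensities = intensities, enrichment = enrichment, fdr = fdr,
    profiles = profiles, unioned = unioned, decisions = decisions,
    final = assembled$final, members = member_tbl,
    summary = summary, evaluation = evaluation, categories = categories
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(out_dir, f)
    write_tsv_table(truth, p("truth.tsv"))
    write_proteome_fasta(truth, p("proteome.fasta"))
    write_observations(observations, p("observations.tsv"))
    for (tx in names(targeting)) {
      write_tsv_table(targeting[[tx]], p(sprintf("targetp_%s.tsv", tx)))
    }
    write_tsv_table(orthologs, p("orthologs.tsv"))
    write_peptides_table(matches, p("peptides.tsv"))
    write_protein_groups_table(
      groups, uniq$counts, intensities, p("proteinGroups.tsv")
    )
    write_tsv_table(enrichment, p("enrichment.tsv"))
    write_tsv_table(decisions, p("decisions.tsv"))
    write_tsv_table(member_tbl, p("final_proteome.tsv"))
    write_tsv_table(categories$categories, p("category_summary.tsv"))
    write_summary_json(summary, p("summary.json"))
    writeLines(log_lines, p("pipeline.log"))
  }
  invisible(out)
}

normalize_pipeline_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) {
      stop("config file not found: ", config, call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  if (inherits(config, "simulation_config")) {
    config <- list(simulate = unclass(config))
  }
  if (!is.list(config)) stop("config must be a list or a path", call. = FALSE)
  sim_args <- config$simulate %||% list()
  if (inherits(sim_args, "simulation_config")) {
    sim <- sim_args
  } else {
    sim <- do.call(simulation_config, sim_args)
  }
  list(
    simulate = sim,
    fdr = list(
      level = config$fdr$level %||% 0.01,
      separation = config$fdr$separation %||% sim$id_score_separation
    ),
    integrate = list(rule = config$integrate$rule %||% "union")
  )
}

#' Recall and precision of the final proteome against ground truth
#'
#' Positives are proteins whose true localization is mitochondrial or
#' dual.
#'
#' @param final_ids Identifiers of the final proteome members.
#' @param truth Ground-truth tibble from [generate_proteome()].
#' @return List: `recall`, `precision`, `tp`, `fp`, `fn`.
#' @export
evaluate_recovery <- function(final_ids, truth) {
  positives <- truth$protein_id[truth$localization %in% c("mito", "dual")]
  tp <- length(intersect(final_ids, positives))
  fp <- length(setdiff(final_ids, positives))
  fn <- length(setdiff(positives, final_ids))
  list(
    recall = if (length(positives) > 0) tp / length(positives) else NA_real_,
    precision = if (length(final_ids) > 0) tp / length(final_ids) else NA_real_,
    tp = tp, fp = fp, fn = fn
  )
}
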