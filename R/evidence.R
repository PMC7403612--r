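# Membership evidence layers: orthology, targeting consensus,
# homology-hit filtering, pathway presence status.

#' Orthology membership against reference mitoproteomes
#'
#' A protein is an accepted orthology member when an orthologous sequence
#' is detected in at least one reference mitoproteome.
#'
#' @param protein_ids Character vector of proteins to score.
#' @param ortholog_table Tibble: `protein_id`, `reference_species`,
#'   `reference_protein`.
#' @param reference_species Character vector of the surveyed reference
#'   mitoproteomes; any other species in the table is an input error.
#' @return Tibble: `protein_id`, `ortholog_member`, `reference_species`
#'   (list column of matched species).
#' @export
ortholog_membership <- function(protein_ids, ortholog_table,
                                reference_species = reference_species_names()) {
  unknown <- setdiff(unique(ortholog_table$reference_species), reference_species)
  if (length(unknown) > 0) {
    stop(
      "ortholog table contains unknown reference species: ",
      paste(unknown, collapse = ", "), call. = FALSE
    )
  }
  sp <- lapply(
    stats::setNames(nm = protein_ids),
    function(id) character()
  )
  hit <- split(
    ortholog_table$reference_species,
    ortholog_table$protein_id
  )
  hit <- lapply(hit, function(x) sort(unique(x)))
  found <- intersect(names(hit), protein_ids)
  sp[found] <- hit[found]
  tibble::tibble(
    protein_id = protein_ids,
    ortholog_member = unname(lengths(sp) > 0),
    reference_species = unname(sp)
  )
}

#' Majority consensus of mitochondrial targeting predictions
#'
#' A transcriptome variant votes for mitochondrial import when its ORF
#' starts with methionine and is predicted mitochondrial (`M`). The
#' consensus is reached when votes exceed half the number of surveyed
#' transcriptomes - all `k` surveyed, not only those containing the
#' transcript - so with the standard three transcriptomes at least two
#' votes are required, and a transcript present in a single transcriptome
#' can never reach consensus.
#'
#' @param predictions Tibble with columns `name`, `loc`, `start_met`
#'   (rows may cover several transcriptomes; absent transcripts simply
#'   have no row).
#' @param protein_ids Proteins to score (defaults to those present).
#' @param k Total number of transcriptomes surveyed (default 3).
#' @return Tibble: `protein_id`, `votes`, `targeting_consensus`.
#' @export
targeting_consensus <- function(predictions,
                                protein_ids = unique(predictions$name),
                                k = 3) {
  votes <- stats::setNames(rep(0L, length(protein_ids)), protein_ids)
  if (nrow(predictions) > 0) {
    voting <- predictions[predictions$loc == "M" & predictions$start_met, ]
    tab <- table(voting$name)
    found <- intersect(names(tab), protein_ids)
    votes[found] <- as.integer(tab[found])
  }
  tibble::tibble(
    protein_id = protein_ids,
    votes = as.integer(votes),
    targeting_consensus = votes > k / 2
  )
}

#' Combine per-transcriptome targeting tables
#'
#' Stacks the per-transcriptome prediction tables (as produced by
#' [simulate_targeting_tables()] or read from TargetP-style TSVs) into
#' the long form consumed by [targeting_consensus()].
#'
#' @param tables Named list of tibbles with columns `name`, `loc`,
#'   `start_met`.
#' @return Long tibble with an added `transcriptome` column.
#' @export
stack_targeting_tables <- function(tables) {
  dplyr::bind_rows(tables, .id = "transcriptome")
}

#' Filter homology hits by tool-specific acceptance rules
#'
#' BLAST hits are accepted at E-value \eqn{\le 10^{-3}} (boundary
#' inclusive); HMM hits require E-value \eqn{\le 10^{-3}} and a bias
#' score strictly below 1. A pure filter: the output is a subset of the
#' input, order preserved, idempotent.
#'
#' @param hits Tibble with columns `query`, `target`, `e_value`, `tool`
#'   (`blast` or `hmm`) and, for HMM hits, `bias`.
#' @param e_max E-value cutoff (default 1e-3).
#' @param bias_max HMM bias cutoff, exclusive (default 1).
#' @return The accepted subset of `hits`.
#' @export
filter_homology_hits <- function(hits, e_max = 1e-3, bias_max = 1) {
  stopifnot(all(c("e_value", "tool") %in% names(hits)))
  if (!all(hits$tool %in% c("blast", "hmm"))) {
    stop("tool must be 'blast' or 'hmm'", call. = FALSE)
  }
  is_hmm <- hits$tool == "hmm"
  if (any(is_hmm)) {
    if (!"bias" %in% names(hits) || anyNA(hits$bias[is_hmm])) {
      stop("hmm hits require a bias score", call. = FALSE)
    }
  }
  keep <- hits$e_value <= e_max
  if (any(is_hmm)) {
    keep[is_hmm] <- keep[is_hmm] & hits$bias[is_hmm] < bias_max
  }
  hits[keep, , drop = FALSE]
}

#' Four-way presence status for pathway components
#'
#' `PROTEOMIC` for components detected in the verified proteome,
#' `PUTATIVE` when detected but supported only by weak homology,
#' `IN_SILICO` for transcriptome-only evidence, `ABSENT` otherwise.
#'
#' @param in_proteome,in_transcriptome,weak_homology_only Logical
#'   vectors (recycled).
#' @return Character vector of statuses.
#' @export
presence_status <- function(in_proteome, in_transcriptome,
                            weak_homology_only = FALSE) {
  n <- max(length(in_proteome), length(in_transcriptome), length(weak_homology_only))
  in_proteome <- rep_len(in_proteome, n)
  in_transcriptome <- rep_len(in_transcriptome, n)
  weak_homology_only <- rep_len(weak_homology_only, n)
  ifelse(in_proteome & weak_homology_only, "PUTATIVE",
    ifelse(in_proteome, "PROTEOMIC",
      ifelse(in_transcriptome, "IN_SILICO", "ABSENT")
    )
  )
}

#' Build per-protein evidence profiles
#'
#' Joins the three membership strategies (orthology, enrichment,
#' targeting consensus) with the annotation and prediction flags into
#' the profile table consumed by [strategy_union()] and [curate()].
#' Enrichment is computed per protein group and inherited by every
#' member protein.
#'
#' @param candidates Tibble with `protein_id` and the annotation flags
#'   `predicted_mito`, `annotation_mito_function`,
#'   `annotation_clear_nonmito` (missing flag columns default to FALSE).
#' @param orthology Output of [ortholog_membership()].
#' @param enrichment Output of [enrichment_ratios()] (per group).
#' @param consensus Output of [targeting_consensus()].
#' @param groups Tibble from [group_proteins()] used to map proteins to
#'   groups; omit if `enrichment` is already per protein with a
#'   `protein_id` column.
#' @return Tibble of evidence profiles, one row per candidate.
#' @export
build_evidence_profiles <- function(candidates, orthology, enrichment,
                                    consensus, groups = NULL) {
  ids <- candidates$protein_id
  if (anyDuplicated(ids)) {
    stop("duplicate candidate identifiers", call. = FALSE)
  }
  flag <- function(col) {
    if (col %in% names(candidates)) candidates[[col]] else rep(FALSE, length(ids))
  }
  orth <- stats::setNames(orthology$ortholog_member, orthology$protein_id)
  cons <- stats::setNames(consensus$targeting_consensus, consensus$protein_id)
  if (!is.null(groups)) {
    lk <- group_lookup(groups)
    enr_by_group <- stats::setNames(enrichment$enriched, enrichment$group_id)
    ratio_by_group <- stats::setNames(enrichment$ratio_mt_cp, enrichment$group_id)
    bin_by_group <- stats::setNames(enrichment$confidence_bin, enrichment$group_id)
    gid <- lk[ids]
    enr <- enr_by_group[gid]
    ratio <- ratio_by_group[gid]
    bin <- bin_by_group[gid]
  } else {
    enr <- stats::setNames(enrichment$enriched, enrichment$protein_id)[ids]
    ratio <- stats::setNames(enrichment$ratio_mt_cp, enrichment$protein_id)[ids]
    bin <- stats::setNames(enrichment$confidence_bin, enrichment$protein_id)[ids]
  }
  tibble::tibble(
    id = ids,
    ortholog_member = unname(orth[ids]) %in% TRUE,
    enriched = unname(enr) %in% TRUE,
    targeting_consensus = unname(cons[ids]) %in% TRUE,
    predicted_mito = flag("predicted_mito"),
    annotation_mito_function = flag("annotation_mito_function"),
    annotation_clear_nonmito = flag("annotation_clear_nonmito"),
    ratio_mt_cp = unname(ratio),
    confidence_bin = unname(bin)
  )
}
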