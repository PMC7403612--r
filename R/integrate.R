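# Union of the three identification strategies, curation (contaminant
# removal, reintegration), and assembly of the final verified proteome.

#' Union of the three identification strategies
#'
#' A candidate enters the accepted union when it satisfies at least one
#' of orthology, enrichment, or targeting consensus; the strategy flags
#' record every satisfied strategy. A strict-majority mode (at least two
#' of three) is available for sensitivity analysis.
#'
#' @param profiles Evidence-profile tibble (see
#'   [build_evidence_profiles()]), one row per candidate; duplicate
#'   identifiers are an input error.
#' @param rule `"union"` (default) or `"majority"`.
#' @return `profiles` with added `strategies` (comma-joined labels from
#'   `ORTHOLOG`, `ENRICHED`, `TARGETING`), `n_strategies`, `in_union`.
#' @export
strategy_union <- function(profiles, rule = c("union", "majority")) {
  rule <- match.arg(rule)
  if (anyDuplicated(profiles$id)) {
    stop("duplicate candidate identifiers", call. = FALSE)
  }
  flags <- cbind(
    ORTHOLOG = profiles$ortholog_member,
    ENRICHED = profiles$enriched,
    TARGETING = profiles$targeting_consensus
  )
  n_strat <- rowSums(flags)
  strategies <- apply(flags, 1, function(f) {
    paste(colnames(flags)[f], collapse = ",")
  })
  out <- profiles
  out$strategies <- strategies
  out$n_strategies <- as.integer(n_strat)
  out$in_union <- if (rule == "union") n_strat >= 1 else n_strat >= 2
  out
}

#' Curate the strategy union
#'
#' Removes union members whose functional annotation shows clear
#' non-mitochondrial function *and* that lack an ortholog in any
#' reference mitoproteome (`REMOVED_CONTAMINANT`); reintegrates
#' non-members that carry both predicted-mitoproteome membership and a
#' mitochondrial functional annotation (`REINTEGRATED`). All other union
#' members stay `ACCEPTED`; all other non-members are `REJECTED`. Every
#' decision carries a rationale string. Curation is stable: re-running
#' it on its own output changes nothing.
#'
#' @param unioned Output of [strategy_union()].
#' @return Tibble of membership decisions: `id`, `strategies`, `status`,
#'   `rationale`, `final_member`.
#' @export
curate <- function(unioned) {
  removed <- unioned$in_union &
    unioned$annotation_clear_nonmito & !unioned$ortholog_member
  reintegrated <- !unioned$in_union &
    unioned$predicted_mito & unioned$annotation_mito_function
  status <- ifelse(removed, "REMOVED_CONTAMINANT",
    ifelse(unioned$in_union, "ACCEPTED",
      ifelse(reintegrated, "REINTEGRATED", "REJECTED")
    )
  )
  rationale <- ifelse(
    status == "REMOVED_CONTAMINANT",
    "clear non-mitochondrial annotation and no ortholog in any reference mitoproteome",
    ifelse(
      status == "ACCEPTED",
      paste0("satisfies strategies: ", unioned$strategies),
      ifelse(
        status == "REINTEGRATED",
        "predicted mitoproteome member with mitochondrial functional annotation",
        "no identification strategy satisfied"
      )
    )
  )
  tibble::tibble(
    id = unioned$id,
    strategies = unioned$strategies,
    status = status,
    rationale = rationale,
    final_member = status %in% c("ACCEPTED", "REINTEGRATED")
  )
}

#' Assemble the final proteome and its summary
#'
#' The final proteome is the accepted union members plus the
#' reintegrated proteins, ordered by identifier. The summary records the
#' candidate count, per-strategy counts, union size, removals,
#' reintegrations, the final count (which must equal
#' union - removed + reintegrated, asserted on every run), and the
#' number of final members retained despite greater chloroplast
#' enrichment (Mt/Cp < 1), which stay in on orthology and/or targeting
#' evidence.
#'
#' @param unioned Output of [strategy_union()].
#' @param decisions Output of [curate()] on the same candidates.
#' @return List: `final` (tibble of final members with provenance),
#'   `summary` (named list of counts).
#' @export
assemble <- function(unioned, decisions) {
  stopifnot(identical(unioned$id, decisions$id))
  final <- decisions[decisions$final_member, , drop = FALSE]
  final <- final[order(final$id), , drop = FALSE]
  n_union <- sum(unioned$in_union)
  n_removed <- sum(decisions$status == "REMOVED_CONTAMINANT")
  n_reint <- sum(decisions$status == "REINTEGRATED")
  n_final <- nrow(final)
  if (n_final != n_union - n_removed + n_reint) {
    stop("internal consistency error: final != union - removed + reintegrated",
      call. = FALSE
    )
  }
  ratio <- unioned$ratio_mt_cp %||% rep(NA_real_, nrow(unioned))
  is_final <- stats::setNames(decisions$final_member, decisions$id)[unioned$id]
  cp_greater <- is_final & !is.na(ratio) & !is.nan(ratio) & ratio < 1 &
    (unioned$ortholog_member | unioned$targeting_consensus)
  summary <- list(
    candidates = nrow(unioned),
    ortholog = sum(unioned$ortholog_member),
    enriched = sum(unioned$enriched),
    targeting = sum(unioned$targeting_consensus),
    union = n_union,
    removed = n_removed,
    reintegrated = n_reint,
    final = n_final,
    retained_cp_greater = sum(cp_greater)
  )
  list(final = final, summary = summary)
}

#' Combined expected proteome size
#'
#' Size of the union of the experimentally verified set and the
#' in-silico predicted set, plus the overlap count (experimentally
#' verified predictions).
#'
#' @param experimental,predicted Character vectors of identifiers.
#' @return List: `total`, `overlap`, `experimental_only`,
#'   `predicted_only`.
#' @export
expected_total <- function(experimental, predicted) {
  experimental <- unique(experimental)
  predicted <- unique(predicted)
  overlap <- length(intersect(experimental, predicted))
  list(
    total = length(union(experimental, predicted)),
    overlap = overlap,
    experimental_only = length(experimental) - overlap,
    predicted_only = length(predicted) - overlap
  )
}
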