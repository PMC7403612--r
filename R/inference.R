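# Identification layer: peptide canonicalisation, peptide-set-subsumption
# protein grouping, unique/razor peptide accounting, target-decoy FDR.

#' Canonicalise and length-filter peptides
#'
#' Isoleucine and leucine are indistinguishable by mass, so every `I` is
#' collapsed to `L`; peptides shorter than `min_length` are removed.
#' Order is preserved and the operation is idempotent.
#'
#' @param peptides Character vector of peptide sequences.
#' @param min_length Minimum peptide length retained (default 6).
#' @return Canonical peptides, in input order.
#' @examples
#' collapse_and_filter(c("PEPTIDE", "AAAAA"))  # "PEPTLDE"
#' @export
collapse_and_filter <- function(peptides, min_length = 6) {
  assert_aa(peptides, "peptide")
  out <- gsub("I", "L", peptides, fixed = TRUE)
  out[nchar(out) >= min_length]
}

#' Build peptide matches from a long observation table
#'
#' Collapses I/L, applies the length filter, merges peptides that become
#' identical after collapsing (their protein sets union, their
#' intensities add), and returns one row per canonical peptide with the
#' set of matched proteins and per-sample intensities in wide form
#' (columns `<fraction>_<replicate>`).
#'
#' @param observations Tibble with columns `peptide`, `protein_ids`
#'   (`;`-separated), `fraction`, `replicate`, `intensity`.
#' @param min_length Minimum peptide length retained.
#' @return Tibble: `peptide`, `proteins` (list column of character
#'   vectors), one numeric column per sample.
#' @export
peptide_matches <- function(observations, min_length = 6) {
  need <- c("peptide", "protein_ids", "fraction", "replicate", "intensity")
  missing_cols <- setdiff(need, names(observations))
  if (length(missing_cols) > 0) {
    stop(
      "observation table lacks columns: ",
      paste(missing_cols, collapse = ", "), call. = FALSE
    )
  }
  if (nrow(observations) == 0) {
    return(tibble::tibble(peptide = character(), proteins = list()))
  }
  obs <- observations
  obs$peptide <- gsub("I", "L", obs$peptide, fixed = TRUE)
  obs <- obs[nchar(obs$peptide) >= min_length, ]
  if (nrow(obs) == 0) {
    return(tibble::tibble(peptide = character(), proteins = list()))
  }
  obs$sample <- paste(obs$fraction, obs$replicate, sep = "_")
  samples <- sort(unique(obs$sample))
  prot <- lapply(
    split(obs$protein_ids, obs$peptide),
    function(x) sort(unique(unlist(strsplit(x, ";", fixed = TRUE))))
  )
  wide <- tibble::tibble(peptide = sort(unique(obs$peptide)))
  wide$proteins <- unname(prot[wide$peptide])
  for (s in samples) {
    sub <- obs[obs$sample == s, ]
    v <- tapply(sub$intensity, sub$peptide, sum)
    col <- stats::setNames(rep(0, nrow(wide)), wide$peptide)
    col[names(v)] <- v
    wide[[s]] <- as.numeric(col)
  }
  wide
}

#' Group proteins by peptide-set subsumption
#'
#' Two proteins join the same group when the identified peptide set of
#' one contains the peptide set of the other. Groups are formed through
#' the leading protein: proteins are visited in order of decreasing
#' peptide-set size (ties broken lexicographically by identifier); each
#' unassigned protein becomes a leader and absorbs every unassigned
#' protein whose peptide set is a subset of the leader's. Proteins with
#' identical sets are co-members. The result is invariant under
#' permutation of the input.
#'
#' @param matches Tibble from [peptide_matches()] (columns `peptide` and
#'   `proteins`), or any tibble with those two columns.
#' @return Tibble: `group_id`, `leader`, `members` (list column),
#'   `n_members`, `n_peptides` (leader's peptide count).
#' @export
group_proteins <- function(matches) {
  if (nrow(matches) == 0) {
    return(tibble::tibble(
      group_id = character(), leader = character(),
      members = list(), n_members = integer(), n_peptides = integer()
    ))
  }
  sets <- protein_peptide_sets(matches)
  ids <- names(sets)
  ord <- order(-lengths(sets), ids)
  assigned <- stats::setNames(rep(FALSE, length(ids)), ids)
  groups <- list()
  for (i in ord) {
    id <- ids[i]
    if (assigned[id]) next
    leader_set <- sets[[id]]
    member_ids <- ids[!assigned &
      vapply(sets, function(s) all(s %in% leader_set), logical(1))]
    assigned[member_ids] <- TRUE
    groups[[length(groups) + 1]] <- list(
      leader = id,
      members = sort(member_ids),
      n_peptides = length(leader_set)
    )
  }
  # deterministic output order: by leader identifier
  groups <- groups[order(vapply(groups, `[[`, character(1), "leader"))]
  tibble::tibble(
    group_id = sprintf("GRP%04d", seq_along(groups)),
    leader = vapply(groups, `[[`, character(1), "leader"),
    members = lapply(groups, `[[`, "members"),
    n_members = vapply(groups, function(g) length(g$members), integer(1)),
    n_peptides = vapply(groups, `[[`, integer(1), "n_peptides")
  )
}

# peptide sets per protein, from a matches tibble
protein_peptide_sets <- function(matches) {
  n_per <- lengths(matches$proteins)
  long <- data.frame(
    protein = unlist(matches$proteins, use.names = FALSE),
    peptide = rep(matches$peptide, n_per),
    stringsAsFactors = FALSE
  )
  lapply(split(long$peptide, long$protein), function(x) sort(unique(x)))
}

#' Count unique peptides per protein group
#'
#' A peptide is unique to a group when every protein it matches belongs
#' to that group; peptides spanning groups are razor peptides and are
#' excluded from the unique counts. Returns per-group unique and razor
#' counts plus the partition of groups into more-than-one, exactly-one,
#' and zero unique peptides.
#'
#' @param groups Tibble from [group_proteins()].
#' @param matches Tibble from [peptide_matches()].
#' @return List with `counts` (tibble: `group_id`, `unique_peptides`,
#'   `razor_peptides`) and `partition` (named counts `multi`, `single`,
#'   `none`).
#' @export
count_unique_peptides <- function(groups, matches) {
  member_group <- group_lookup(groups)
  pep_groups <- lapply(
    matches$proteins,
    function(p) unique(member_group[p])
  )
  n_groups_per_pep <- lengths(pep_groups)
  unique_counts <- stats::setNames(rep(0L, nrow(groups)), groups$group_id)
  razor_counts <- unique_counts
  for (i in seq_along(pep_groups)) {
    gs <- pep_groups[[i]]
    if (length(gs) == 1) {
      unique_counts[gs] <- unique_counts[gs] + 1L
    } else {
      razor_counts[gs] <- razor_counts[gs] + 1L
    }
  }
  counts <- tibble::tibble(
    group_id = groups$group_id,
    unique_peptides = as.integer(unique_counts),
    razor_peptides = as.integer(razor_counts)
  )
  list(
    counts = counts,
    partition = c(
      multi = sum(counts$unique_peptides > 1),
      single = sum(counts$unique_peptides == 1),
      none = sum(counts$unique_peptides == 0)
    )
  )
}

# named vector: protein id -> group id
group_lookup <- function(groups) {
  stats::setNames(
    rep(groups$group_id, groups$n_members),
    unlist(groups$members, use.names = FALSE)
  )
}

#' Target-decoy FDR threshold
#'
#' Sorts entries by decreasing score and returns the most permissive
#' (lowest) threshold at which the decoy-based FDR estimate
#' `decoys / targets` does not exceed `level`. Targets above the
#' threshold form the accepted set; a qualifying prefix containing no
#' target yields an empty acceptance with FDR defined as 0.
#'
#' @param scored Tibble with columns `score` and `is_decoy` (and
#'   optionally `id`). Decoys may also be flagged by a `REV__` identifier
#'   prefix via [decoy_from_ids()].
#' @param level Requested FDR level (default 0.01).
#' @return List: `threshold`, `accepted_targets`, `accepted_decoys`,
#'   `fdr`, and `accepted` (tibble of accepted target rows, sorted by
#'   decreasing score).
#' @export
decoy_fdr_threshold <- function(scored, level = 0.01) {
  stopifnot(all(c("score", "is_decoy") %in% names(scored)))
  if (!any(!scored$is_decoy)) {
    return(list(
      threshold = Inf, accepted_targets = 0L, accepted_decoys = 0L,
      fdr = 0, accepted = scored[0, , drop = FALSE]
    ))
  }
  ord <- order(-scored$score, scored$is_decoy)
  s <- scored[ord, , drop = FALSE]
  cum_t <- cumsum(!s$is_decoy)
  cum_d <- cumsum(s$is_decoy)
  fdr_hat <- ifelse(cum_t == 0, 0, cum_d / pmax(cum_t, 1))
  ok <- which(fdr_hat <= level)
  if (length(ok) == 0 || max(cum_t[ok]) == 0) {
    return(list(
      threshold = Inf, accepted_targets = 0L, accepted_decoys = 0L,
      fdr = 0, accepted = s[0, , drop = FALSE]
    ))
  }
  # most permissive qualifying cutoff by accepted targets; among ties the
  # shortest prefix, so the threshold sits at the last accepted target and
  # a trailing run of pure decoys is never swept in
  best_t <- max(cum_t[ok])
  i <- min(ok[cum_t[ok] == best_t])
  accepted <- s[seq_len(i), , drop = FALSE]
  list(
    threshold = s$score[i],
    accepted_targets = as.integer(cum_t[i]),
    accepted_decoys = as.integer(cum_d[i]),
    fdr = if (cum_t[i] == 0) 0 else cum_d[i] / cum_t[i],
    accepted = accepted[!accepted$is_decoy, , drop = FALSE]
  )
}

#' Flag decoys by reversed-database identifier prefix
#'
#' @param ids Character identifiers; reversed-database entries carry the
#'   `REV__` prefix.
#' @return Logical vector.
#' @export
decoy_from_ids <- function(ids) {
  startsWith(ids, "REV__")
}
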