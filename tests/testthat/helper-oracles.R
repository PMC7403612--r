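# Independent oracles and random-instance generators shared across tests.

# Brute-force grouping oracle: explicit all-pairs subset tests and
# closure through the leading protein, written as plain loops over a
# subset matrix (independent of the package's vectorised path).
oracle_group_proteins <- function(sets) {
  ids <- names(sets)
  n <- length(ids)
  subset_of <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      subset_of[i, j] <- all(sets[[i]] %in% sets[[j]])
    }
  }
  assigned <- rep(FALSE, n)
  groups <- list()
  repeat {
    open <- which(!assigned)
    if (length(open) == 0) break
    # next leader: largest peptide set, ties lexicographic by id
    sizes <- vapply(open, function(i) length(sets[[i]]), integer(1))
    best <- open[sizes == max(sizes)]
    leader <- best[order(ids[best])][1]
    members <- open[subset_of[open, leader]]
    assigned[members] <- TRUE
    groups[[length(groups) + 1]] <- list(
      leader = ids[leader], members = sort(ids[members])
    )
  }
  groups[order(vapply(groups, `[[`, character(1), "leader"))]
}

# Random peptide-to-protein instance for grouping tests.
random_matches <- function(n_proteins, n_peptides) {
  proteins <- sprintf("P%02d", seq_len(n_proteins))
  peptides <- sprintf("PEPTLDE%03d", seq_len(n_peptides))
  sets <- lapply(proteins, function(p) {
    sort(sample(peptides, sample.int(n_peptides, 1)))
  })
  names(sets) <- proteins
  used <- sort(unique(unlist(sets)))
  tibble::tibble(
    peptide = used,
    proteins = lapply(used, function(pep) {
      sort(proteins[vapply(sets, function(s) pep %in% s, logical(1))])
    })
  )
}

# Peptide sets per protein from a matches tibble (test-side).
matches_to_sets <- function(matches) {
  proteins <- sort(unique(unlist(matches$proteins)))
  sets <- lapply(proteins, function(p) {
    sort(matches$peptide[vapply(
      matches$proteins, function(x) p %in% x, logical(1)
    )])
  })
  names(sets) <- proteins
  sets
}

# Compare package grouping with the oracle on one instance.
expect_grouping_matches_oracle <- function(matches) {
  got <- group_proteins(matches)
  want <- oracle_group_proteins(matches_to_sets(matches))
  expect_equal(nrow(got), length(want))
  expect_equal(got$leader, vapply(want, `[[`, character(1), "leader"))
  expect_equal(got$members, lapply(want, `[[`, "members"))
}

random_aa_string <- function(len) {
  paste(
    sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len, replace = TRUE),
    collapse = ""
  )
}

# Small wide intensity table for quantification tests.
make_intensities <- function(group_id, mt, cp, wc) {
  out <- tibble::tibble(group_id = group_id, quantifiable = TRUE)
  for (i in seq_along(mt[[1]])) out[[paste0("mt_", i)]] <- vapply(mt, `[`, numeric(1), i)
  for (i in seq_along(cp[[1]])) out[[paste0("cp_", i)]] <- vapply(cp, `[`, numeric(1), i)
  for (i in seq_along(wc[[1]])) out[[paste0("wc_", i)]] <- vapply(wc, `[`, numeric(1), i)
  out
}
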