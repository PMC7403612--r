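# Identification layer: canonicalisation, subsumption grouping,
# unique/razor accounting, target-decoy FDR.

test_that("I/L collapse and length filter behave and are idempotent", {
  expect_equal(collapse_and_filter("PEPTIDE"), "PEPTLDE")
  expect_equal(collapse_and_filter("AAAAA"), character())
  expect_error(collapse_and_filter("PEPT1DE"), "alphabet")

  set.seed(21)
  peps <- vapply(sample(4:15, 500, replace = TRUE), random_aa_string, character(1))
  once <- collapse_and_filter(peps)
  expect_identical(collapse_and_filter(once), once)
  # order preserved
  expect_identical(once, gsub("I", "L", peps[nchar(peps) >= 6]))
})

make_matches <- function(assignments) {
  # assignments: named list protein -> peptide vector
  peps <- sort(unique(unlist(assignments)))
  tibble::tibble(
    peptide = peps,
    proteins = lapply(peps, function(p) {
      sort(names(assignments)[vapply(assignments, function(s) p %in% s, logical(1))])
    })
  )
}

test_that("subset peptide sets collapse into one group with the right leader", {
  m <- make_matches(list(
    A = c("p1", "p2", "p3"), B = c("p1", "p2"), C = "p4"
  ))
  g <- group_proteins(m)
  expect_equal(nrow(g), 2)
  expect_equal(g$leader, c("A", "C"))
  expect_equal(g$members, list(c("A", "B"), "C"))
})

test_that("identical peptide sets become co-members, leader by identifier", {
  g <- group_proteins(make_matches(list(B = "p1", A = "p1")))
  expect_equal(nrow(g), 1)
  expect_equal(g$leader, "A")
  expect_equal(g$members[[1]], c("A", "B"))
})

test_that("overlapping but non-nested sets stay separate with a razor peptide", {
  m <- make_matches(list(A = c("p1", "p2"), B = c("p2", "p3")))
  g <- group_proteins(m)
  expect_equal(nrow(g), 2)
  uc <- count_unique_peptides(g, m)
  expect_equal(uc$counts$unique_peptides, c(1L, 1L)) # p1 and p3
  expect_equal(uc$counts$razor_peptides, c(1L, 1L)) # p2 on both sides
})

test_that("grouping is invariant under permutation of the input rows", {
  set.seed(31)
  for (i in 1:20) {
    m <- random_matches(8, 15)
    g1 <- group_proteins(m)
    g2 <- group_proteins(m[sample.int(nrow(m)), ])
    expect_identical(g1, g2)
  }
})

test_that("grouping equals the brute-force oracle on random instances", {
  set.seed(41)
  for (i in 1:40) {
    expect_grouping_matches_oracle(random_matches(
      sample(2:12, 1), sample(3:25, 1)
    ))
  }
})

test_that("unique peptides are counted per group and razors excluded", {
  m <- make_matches(list(A = c("p1", "p2"), B = c("p1", "p2")))
  g <- group_proteins(m)
  uc <- count_unique_peptides(g, m)
  expect_equal(uc$counts$unique_peptides, 2L) # both unique to the {A,B} group
  expect_equal(unname(uc$partition), c(1L, 0L, 0L))

  set.seed(51)
  for (i in 1:25) {
    m <- random_matches(6, 20)
    g <- group_proteins(m)
    uc <- count_unique_peptides(g, m)
    # unique and razor peptides partition the peptide list
    expect_lte(sum(uc$counts$unique_peptides), nrow(m))
    lk <- setNames(rep(g$group_id, g$n_members), unlist(g$members))
    n_razor <- sum(vapply(
      m$proteins, function(p) length(unique(lk[p])) > 1, logical(1)
    ))
    expect_equal(sum(uc$counts$unique_peptides) + n_razor, nrow(m))
  }
})

test_that("FDR threshold picks the most permissive qualifying cutoff", {
  scored <- tibble::tibble(
    score = c(10, 9, 8, 7, 6),
    is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE)
  )
  res <- decoy_fdr_threshold(scored, level = 0.01)
  expect_equal(res$threshold, 7)
  expect_equal(res$accepted_targets, 4L)
  expect_equal(res$accepted_decoys, 0L)
  expect_equal(res$fdr, 0)

  res2 <- decoy_fdr_threshold(
    tibble::tibble(score = c(10, 11), is_decoy = c(FALSE, TRUE)),
    level = 0.01
  )
  expect_equal(res2$accepted_targets, 0L)
  expect_equal(nrow(res2$accepted), 0)
  expect_equal(res2$fdr, 0)

  all_decoys <- tibble::tibble(score = c(3, 2), is_decoy = TRUE)
  res3 <- decoy_fdr_threshold(all_decoys)
  expect_equal(res3$accepted_targets, 0L)
  expect_equal(res3$fdr, 0)
})

test_that("estimated FDR never exceeds the level and is monotone in it", {
  set.seed(61)
  for (i in 1:20) {
    scored <- simulate_decoy_scores(300, 300, separation = 2.5, seed = i)
    prev <- Inf
    for (level in c(0.2, 0.1, 0.05, 0.01)) {
      res <- decoy_fdr_threshold(scored, level = level)
      expect_lte(res$fdr, level)
      n_acc <- res$accepted_targets + res$accepted_decoys
      expect_lte(n_acc, prev) # lowering level never admits more entries
      prev <- n_acc
    }
  }
})

test_that("reversed-database identifiers flag decoys", {
  expect_equal(
    decoy_from_ids(c("EG00001", "REV__EG00001")),
    c(FALSE, TRUE)
  )
})
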