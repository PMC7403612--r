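# Evidence layers: orthology, targeting consensus, homology-hit
# filtering, presence status, format readers.

test_that("orthology membership needs at least one reference hit", {
  refs <- reference_species_names(4)
  tab <- tibble::tibble(
    protein_id = c("a", "c", "c", "c", "c"),
    reference_species = c(refs[1], refs),
    reference_protein = paste0("x", 1:5)
  )
  res <- ortholog_membership(c("a", "b", "c"), tab, refs)
  expect_equal(res$ortholog_member, c(TRUE, FALSE, TRUE))
  expect_equal(res$reference_species[[1]], refs[1])
  expect_equal(res$reference_species[[3]], sort(refs))

  bad <- tibble::tibble(
    protein_id = "a", reference_species = "H_sapiens", reference_protein = "y"
  )
  expect_error(ortholog_membership("a", bad, refs), "unknown reference species")
})

test_that("targeting consensus counts methionine-start mito votes over all k", {
  pred <- function(...) {
    rows <- list(...)
    tibble::tibble(
      name = "p",
      loc = vapply(rows, `[[`, character(1), 1),
      start_met = vapply(rows, function(r) as.logical(r[[2]]), logical(1))
    )
  }
  expect_true(targeting_consensus(
    pred(c("M", TRUE), c("M", TRUE), c("S", TRUE)), "p"
  )$targeting_consensus)
  # a no-methionine entry does not vote, but the other two suffice
  res <- targeting_consensus(
    pred(c("M", FALSE), c("M", TRUE), c("M", TRUE)), "p"
  )
  expect_true(res$targeting_consensus)
  expect_equal(res$votes, 2L)
  # present in a single transcriptome: 1 vote < 2 needed of 3 surveyed
  expect_false(targeting_consensus(pred(c("M", TRUE)), "p")$targeting_consensus)
  # no predictions at all
  empty <- targeting_consensus(
    tibble::tibble(name = character(), loc = character(), start_met = logical()),
    "p"
  )
  expect_false(empty$targeting_consensus)
})

test_that("homology hits honour tool-specific thresholds", {
  hits <- tibble::tibble(
    query = c("q1", "q2", "q3", "q4"),
    target = c("t1", "t2", "t3", "t4"),
    e_value = c(1e-3, 1e-5, 1e-4, 0.1),
    bias = c(NA, 1.0, 0.2, 0.1),
    tool = c("blast", "hmm", "hmm", "blast")
  )
  acc <- filter_homology_hits(hits)
  # blast at the 1e-3 boundary accepted; hmm bias 1.0 rejected (strict)
  expect_equal(acc$query, c("q1", "q3"))
  # pure filter: subset, order preserved, idempotent
  expect_identical(filter_homology_hits(acc), acc)
  expect_true(all(acc$query %in% hits$query))

  no_bias <- tibble::tibble(
    query = "q", target = "t", e_value = 1e-5, tool = "hmm"
  )
  expect_error(filter_homology_hits(no_bias), "bias")
})

test_that("presence status maps the four evidence patterns", {
  expect_equal(presence_status(TRUE, TRUE, FALSE), "PROTEOMIC")
  expect_equal(presence_status(FALSE, TRUE, FALSE), "IN_SILICO")
  expect_equal(presence_status(TRUE, TRUE, TRUE), "PUTATIVE")
  expect_equal(presence_status(FALSE, FALSE, FALSE), "ABSENT")
  # vectorised
  expect_equal(
    presence_status(c(TRUE, FALSE), c(TRUE, FALSE)),
    c("PROTEOMIC", "ABSENT")
  )
})

test_that("all three evidence flags hold under perfect ancillary data", {
  cfg <- simulation_config(
    n_proteins = 80, truncation_prob = 0, reference_coverage = 1,
    ortholog_fp_rate = 0, targeting_fp_rate = 0, seed = 12
  )
  truth <- generate_proteome(cfg)
  mito <- truth$protein_id[truth$localization %in% c("mito", "dual")]
  orth <- ortholog_membership(
    mito, simulate_ortholog_tables(truth, cfg),
    reference_species_names(cfg$n_reference_proteomes)
  )
  expect_true(all(orth$ortholog_member))
  cons <- targeting_consensus(
    stack_targeting_tables(simulate_targeting_tables(truth, cfg)),
    protein_ids = mito
  )
  expect_true(all(cons$targeting_consensus))
})

test_that("BLAST, HMMER and TargetP readers parse their formats", {
  blast_path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "q1\tt1\t98.2\t120\t2\t0\t1\t120\t5\t124\t1e-30\t250",
    "q2\tt2\t45.0\t80\t30\t2\t1\t80\t1\t78\t0.5\t40"
  ), blast_path)
  b <- read_blast_tab(blast_path)
  expect_equal(b$e_value, c(1e-30, 0.5))
  expect_true(all(b$tool == "blast"))
  expect_equal(nrow(filter_homology_hits(b)), 1)

  hmm_path <- tempfile(fileext = ".txt")
  writeLines(c(
    "# comment line",
    "t1 - profileA - 1e-10 55.2 0.3 1e-9 50 0.2 1 1 0 0 1 1 1 1 -",
    "t2 - profileA - 2e-4 20.1 1.4 1e-3 18 1.2 1 1 0 0 1 1 1 1 -"
  ), hmm_path)
  h <- read_hmmer_tblout(hmm_path)
  expect_equal(h$target, c("t1", "t2"))
  expect_equal(h$bias, c(0.3, 1.4))
  empty_path <- tempfile(fileext = ".txt")
  writeLines("# only comments", empty_path)
  expect_equal(nrow(read_hmmer_tblout(empty_path)), 0)
  expect_equal(nrow(filter_homology_hits(h)), 1) # t2 fails the bias rule

  tp_path <- tempfile(fileext = ".tsv")
  writeLines(c(
    "name\tloc\tRC\tstart_met",
    "p1\tM\t2\tTRUE",
    "p2\tS\t4\tFALSE"
  ), tp_path)
  tp <- read_targetp(tp_path)
  expect_equal(tp$loc, c("M", "S"))
  expect_identical(tp$start_met, c(TRUE, FALSE))
})
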