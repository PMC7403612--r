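# Integration: strategy union, curation, assembly, expected totals.

make_profiles <- function(o = character(), e = character(), t = character(),
                          ids = NULL, clear_nonmito = character(),
                          predicted = character(), annotated = character(),
                          ratio = NULL) {
  ids <- ids %||% sort(unique(c(o, e, t, clear_nonmito, predicted, annotated)))
  tibble::tibble(
    id = ids,
    ortholog_member = ids %in% o,
    enriched = ids %in% e,
    targeting_consensus = ids %in% t,
    predicted_mito = ids %in% predicted,
    annotation_mito_function = ids %in% annotated,
    annotation_clear_nonmito = ids %in% clear_nonmito,
    ratio_mt_cp = ratio %||% rep(2, length(ids))
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("strategy union accepts any single strategy and records flags", {
  u <- strategy_union(make_profiles(
    o = c("a", "b"), e = c("b", "c"), t = "d", ids = c("a", "b", "c", "d", "x")
  ))
  expect_equal(u$id[u$in_union], c("a", "b", "c", "d"))
  expect_equal(u$strategies[u$id == "b"], "ORTHOLOG,ENRICHED")
  expect_equal(u$n_strategies[u$id == "x"], 0L)

  none <- strategy_union(make_profiles(ids = c("p", "q")))
  expect_equal(sum(none$in_union), 0)

  dup <- make_profiles(ids = c("a", "a"))
  expect_error(strategy_union(dup), "duplicate")
})

test_that("union size obeys inclusion-exclusion bounds on random sets", {
  set.seed(91)
  pool <- sprintf("r%03d", 1:60)
  for (i in 1:30) {
    o <- sample(pool, sample(0:30, 1))
    e <- sample(pool, sample(0:30, 1))
    t <- sample(pool, sample(0:30, 1))
    u <- strategy_union(make_profiles(o = o, e = e, t = t, ids = pool))
    n_union <- sum(u$in_union)
    expect_lte(n_union, length(o) + length(e) + length(t))
    expect_equal(n_union, length(unique(c(o, e, t))))
    disjoint <- length(intersect(o, e)) == 0 &&
      length(intersect(o, t)) == 0 && length(intersect(e, t)) == 0
    if (disjoint) {
      expect_equal(n_union, length(o) + length(e) + length(t))
    }
  }
})

test_that("strict-majority mode needs at least two strategies", {
  p <- make_profiles(o = c("a", "b"), e = "b", ids = c("a", "b", "c"))
  u <- strategy_union(p, rule = "majority")
  expect_equal(u$id[u$in_union], "b")
})

test_that("curation removes and reintegrates by the conjunction rules", {
  p <- make_profiles(
    e = c("m1", "m2"), o = "m2",
    ids = c("m1", "m2", "n1", "n2"),
    clear_nonmito = c("m1", "m2"),
    predicted = c("n1", "n2"), annotated = "n1"
  )
  d <- curate(strategy_union(p))
  # member with clear-nonmito annotation and no ortholog: removed
  expect_equal(d$status[d$id == "m1"], "REMOVED_CONTAMINANT")
  # member with clear-nonmito annotation but an ortholog: stays accepted
  expect_equal(d$status[d$id == "m2"], "ACCEPTED")
  # non-member with prediction and annotation: reintegrated
  expect_equal(d$status[d$id == "n1"], "REINTEGRATED")
  # prediction alone is not enough
  expect_equal(d$status[d$id == "n2"], "REJECTED")
  expect_true(all(nzchar(d$rationale)))

  # stability: curating the same union twice yields identical decisions
  expect_identical(curate(strategy_union(p)), d)
})

test_that("assembly enforces final = union - removed + reintegrated", {
  p <- make_profiles(
    e = sprintf("m%02d", 1:10),
    ids = c(sprintf("m%02d", 1:10), sprintf("n%02d", 1:5)),
    clear_nonmito = c("m01", "m02"),
    predicted = c("n01", "n02", "n03"), annotated = c("n01", "n02", "n03")
  )
  u <- strategy_union(p)
  res <- assemble(u, curate(u))
  expect_equal(res$summary$union, 10)
  expect_equal(res$summary$removed, 2)
  expect_equal(res$summary$reintegrated, 3)
  expect_equal(res$summary$final, 11)
  expect_equal(nrow(res$final), 11)

  # no curation: final = union
  p0 <- make_profiles(e = c("a", "b"), ids = c("a", "b", "z"))
  u0 <- strategy_union(p0)
  res0 <- assemble(u0, curate(u0))
  expect_equal(res0$summary$final, res0$summary$union)

  set.seed(92)
  for (i in 1:20) {
    pool <- sprintf("p%03d", 1:40)
    p <- make_profiles(
      o = sample(pool, sample(0:20, 1)),
      e = sample(pool, sample(0:20, 1)),
      t = sample(pool, sample(0:10, 1)),
      ids = pool,
      clear_nonmito = sample(pool, sample(0:10, 1)),
      predicted = sample(pool, sample(0:10, 1)),
      annotated = sample(pool, sample(0:10, 1))
    )
    u <- strategy_union(p)
    res <- assemble(u, curate(u))
    expect_equal(
      res$summary$final,
      res$summary$union - res$summary$removed + res$summary$reintegrated
    )
  }
})

test_that("chloroplast-greater members are retained via orthology or targeting", {
  p <- make_profiles(
    o = c("a", "b"), t = "c", e = "d",
    ids = c("a", "b", "c", "d"),
    ratio = c(0.5, 2, 0.8, 3)
  )
  u <- strategy_union(p)
  res <- assemble(u, curate(u))
  # a (ortholog, ratio 0.5) and c (targeting, ratio 0.8) are retained
  # despite greater chloroplast enrichment; b and d have Mt/Cp > 1
  expect_equal(res$summary$retained_cp_greater, 2)
})

test_that("expected totals count the union and overlap of the two sets", {
  res <- expected_total(c("a", "b"), c("b", "c"))
  expect_equal(res$total, 3)
  expect_equal(res$overlap, 1)

  disjoint <- expected_total(c("a", "b"), c("c", "d"))
  expect_equal(disjoint$total, 4)
  expect_equal(disjoint$overlap, 0)

  set.seed(93)
  for (i in 1:20) {
    x <- sample(letters, sample(0:20, 1))
    y <- sample(letters, sample(0:20, 1))
    r <- expected_total(x, y)
    expect_lte(r$overlap, min(length(x), length(y)))
    expect_equal(r$total, r$experimental_only + r$predicted_only + r$overlap)
  }
})
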