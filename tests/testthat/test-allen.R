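test_that("classify returns the defining relation on worked examples", {
  q <- query_interval("chr1", 2, 5)
  expect_equal(allen_classify(genomic_intervals("chr1", 1, 3), q), "o")
  expect_equal(allen_classify(genomic_intervals("chr1", 2, 5), q), "=")
  expect_equal(allen_classify(genomic_intervals("chr1", 0, 2), q), "m")
  expect_equal(allen_classify(genomic_intervals("chr1", 5, 9), q), "mi")
  expect_equal(allen_classify(genomic_intervals("chr1", 3, 4), q), "d")
  expect_equal(allen_classify(genomic_intervals("chr1", 0, 9), q), "di")
  expect_equal(allen_classify(genomic_intervals("chr1", 2, 4), q), "s")
  expect_equal(allen_classify(genomic_intervals("chr1", 2, 9), q), "si")
  expect_equal(allen_classify(genomic_intervals("chr1", 3, 5), q), "f")
  expect_equal(allen_classify(genomic_intervals("chr1", 1, 5), q), "fi")
  expect_equal(allen_classify(genomic_intervals("chr1", 0, 1), q), "<")
  expect_equal(allen_classify(genomic_intervals("chr1", 7, 9), q), ">")
  expect_equal(allen_classify(genomic_intervals("chr1", 1, 9), q), "di")
})

test_that("classify rejects pairs on different chromosomes", {
  a <- genomic_intervals("chr1", 1, 3)
  expect_error(allen_classify(a, query_interval("chr2", 2, 5)), "incomparable")
})

test_that("all 13 relations occur over small exhaustive enumerations", {
  for (N in c(4, 6)) {
    S <- enumerate_intervals(N)
    rel <- unlist(lapply(seq_len(nrow(S)), function(i) {
      allen_classify(S, S[i, , drop = FALSE])
    }))
    expect_setequal(unique(rel), allen_relations())
  }
})

test_that("exactly one relation holds for every pair (partition property)", {
  S <- enumerate_intervals(6)
  for (i in seq_len(nrow(S))) {
    q <- S[i, , drop = FALSE]
    holds <- vapply(allen_relations(), function(r) sum(relation_holds(S, q, r)),
                    integer(1))
    expect_equal(sum(holds), nrow(S))  # each of the 441 pairs counted once
    cls <- allen_classify(S, q)
    for (r in allen_relations()) {
      expect_equal(relation_holds(S, q, r), cls == r)
    }
  }
})

test_that("converse symmetry: a r q iff q converse(r) a", {
  S <- enumerate_intervals(5)
  for (i in seq_len(nrow(S))) {
    q <- S[i, , drop = FALSE]
    fwd <- allen_classify(S, q)
    bwd <- vapply(seq_len(nrow(S)), function(j) {
      allen_classify(q, S[j, , drop = FALSE])
    }, character(1))
    expect_equal(vapply(fwd, allen_converse, character(1), USE.NAMES = FALSE),
                 bwd)
  }
})

test_that("the 11 intersecting relations coincide with the overlap test", {
  S <- enumerate_intervals(6)
  for (i in seq_len(nrow(S))) {
    q <- S[i, , drop = FALSE]
    rel <- allen_classify(S, q)
    overlaps <- S$start <= q$end & S$end >= q$start
    expect_equal(rel %in% intersecting_relations(), overlaps)
  }
})

test_that("rewrite produces the documented boxes", {
  b <- allen_rewrite("d", query_interval("chr1", 2, 10))
  expect_equal(b$x_low$value, 2);  expect_false(b$x_low$closed)
  expect_equal(b$x_high$value, 10); expect_false(b$x_high$closed)
  expect_equal(b$y_low$value, 2);  expect_false(b$y_low$closed)
  expect_equal(b$y_high$value, 10); expect_false(b$y_high$closed)

  b <- allen_rewrite("oi", query_interval("chr1", 3, 7))
  expect_equal(b$x_low$value, 3);  expect_false(b$x_low$closed)
  expect_equal(b$x_high$value, 7); expect_false(b$x_high$closed)
  expect_equal(b$y_low$value, 7);  expect_false(b$y_low$closed)
  expect_equal(b$y_high$value, Inf)

  b <- allen_rewrite("=", query_interval("chr1", 4, 9))
  expect_true(b$x_low$closed && b$x_high$closed)
  expect_equal(c(b$x_low$value, b$x_high$value), c(4, 4))
  expect_equal(c(b$y_low$value, b$y_high$value), c(9, 9))

  # before/after are half-unbounded
  b <- allen_rewrite("<", query_interval("chr1", 4, 9))
  expect_equal(b$x_low$value, -Inf)
  expect_equal(b$y_high$value, 4); expect_false(b$y_high$closed)
  b <- allen_rewrite("gt", query_interval("chr1", 4, 9))
  expect_equal(b$x_low$value, 9); expect_false(b$x_low$closed)
  expect_equal(b$y_high$value, Inf)
})

test_that("rewriting is sound: classify(a,q) = r iff point in rewrite(r,q)", {
  S <- enumerate_intervals(6)
  for (i in seq_len(nrow(S))) {
    q <- S[i, , drop = FALSE]
    cls <- allen_classify(S, q)
    for (r in allen_relations()) {
      inbox <- point_in_box(S$start, S$end, allen_rewrite(r, q))
      expect_equal(inbox, cls == r)
    }
  }
})

test_that("relation_holds agrees with box membership on random triples", {
  set.seed(7)
  S <- generate_uniform(1000, 40, seed = 11)
  for (k in 1:20) {
    q <- generate_queries(S, 1, seed = 100 + k)
    r <- sample(allen_relations(), 1)
    expect_equal(relation_holds(S, q, r),
                 point_in_box(S$start, S$end, allen_rewrite(r, q)))
  }
})

test_that("an interval starting at coordinate 0 is never dropped by rewriting", {
  # the printed lower bound "0 < x" is a no-constraint side, not x > 0
  a <- genomic_intervals("chr1", 0, 3)
  q <- query_interval("chr1", 2, 5)
  expect_equal(allen_classify(a, q), "o")
  expect_true(point_in_box(0, 3, allen_rewrite("o", q)))
})

test_that("coarse types map to their refined relation sets", {
  expect_setequal(coarse_relation_set("any"), intersecting_relations())
  expect_length(coarse_relation_set("any"), 11)
  expect_setequal(coarse_relation_set("within"), c("d", "s", "f", "="))
  expect_setequal(coarse_relation_set("start"), c("s", "si", "="))
  expect_setequal(coarse_relation_set("end"), c("f", "fi", "="))
  expect_equal(coarse_relation_set("equal"), "=")
  expect_error(coarse_relation_set("overlapping"), "unknown coarse")
})

test_that("relation symbols accept lt/gt/eq aliases and reject junk", {
  expect_equal(as_relation("lt"), "<")
  expect_equal(as_relation("gt"), ">")
  expect_equal(as_relation("eq"), "=")
  expect_equal(as_relation("oi"), "oi")
  expect_error(as_relation("during"), "unknown Allen relation")
})

test_that("invalid intervals and bounds are rejected at construction", {
  expect_error(genomic_intervals("chr1", 5, 5), "strictly less")
  expect_error(genomic_intervals("chr1", 6, 5), "strictly less")
  expect_error(bound(Inf, closed = TRUE), "open")
  expect_error(range_box(bound(3), bound(1), bound(0), bound(9)), "exceeds")
})
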