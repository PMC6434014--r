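test_that("an empty set builds an empty, valid tree", {
  S0 <- genomic_intervals("chr1", numeric(0), numeric(0), integer(0))
  it <- build_it(S0)
  expect_equal(it$n, 0L)
  expect_true(it_validate(it))
  expect_length(query_overlap_it(it, query_interval("chr1", 1, 5)), 0)
  expect_length(query_relation_it(it, query_interval("chr1", 1, 5), "o"), 0)
})

test_that("red-black and max-end invariants hold after every insertion", {
  S <- generate_uniform(800, 100, seed = 23)  # heavy duplication of starts
  it <- build_it(S, audit = TRUE)
  expect_equal(it$audit_violations, 0L)
  expect_true(it_validate(it))
  expect_equal(it$n, 800L)
  # also on adversarial shapes (sorted, reversed, all-identical input)
  chain <- nested_chain(120)
  expect_equal(build_it(chain, audit = TRUE)$audit_violations, 0L)
  rev_chain <- genomic_intervals("chrA", rev(chain$start), rev(chain$end),
                                 chain$index)
  expect_equal(build_it(rev_chain, audit = TRUE)$audit_violations, 0L)
  ident <- adversarial_suite()$identical
  expect_equal(build_it(ident, audit = TRUE)$audit_violations, 0L)
})

test_that("in-order traversal yields keys sorted by (start, end, index)", {
  for (seed in 1:5) {
    S <- generate_uniform(sample(2:400, 1), 50, seed = 60 + seed)
    it <- build_it(S)
    expect_equal(it_inorder(it), S$index[order(S$start, S$end, S$index)])
  }
})

test_that("overlap query equals the closed-interval scan", {
  S <- generate_uniform(600, 80, seed = 29)
  it <- build_it(S)
  # disjoint beyond all data
  expect_length(query_overlap_it(it, query_interval("chrS", 500, 600)), 0)
  for (k in 1:15) {
    q <- generate_queries(S, 1, seed = 70 + k)
    want <- sort(S$index[S$start <= q$end & S$end >= q$start])
    expect_same_ids(query_overlap_it(it, q), want)
  }
})

test_that("overlap equals the union of the 11 refined RTFC queries", {
  S <- generate_uniform(300, 40, seed = 37)
  it <- build_it(S)
  tr <- build_rtfc(S)
  for (k in 1:8) {
    q <- generate_queries(S, 1, seed = 80 + k)
    refined <- sort(unlist(lapply(intersecting_relations(), function(r) {
      as.integer(query_rtfc(tr, q, r))
    })))
    expect_same_ids(query_overlap_it(it, q), refined)
  }
})

test_that("refined relation queries equal the oracle, including < and >", {
  for (k in 1:25) {
    inst <- random_instance(seed = 1300 + k, n = sample(16:512, 1))
    it <- build_it(inst$S)
    for (r in allen_relations()) {
      expect_same_ids(query_relation_it(it, inst$q, r),
                      brute_interval_query(inst$S, inst$q, r))
    }
  }
  # a relation known absent from a crafted fixture
  touching <- adversarial_suite()$touching
  it <- build_it(touching)
  expect_length(query_relation_it(it, query_interval("chrA", 10, 20), "d"), 0)
})

test_that("IT inspects ~m candidates where RTFC touches ~log n + k", {
  # dense-overlap fixture: every interval overlaps q, almost none are o
  n <- 2000
  S <- nested_chain(n)
  mid <- query_interval("chrA", n - 5, n + 5)
  it <- build_it(S)
  tr <- build_rtfc(S)
  got_it <- query_relation_it(it, mid, "o")
  got_rt <- query_rtfc(tr, mid, "o")
  expect_equal(as.integer(got_it), as.integer(got_rt))
  m <- length(query_overlap_it(it, mid))
  k <- length(got_rt)
  expect_gte(m, n - 20)          # nearly everything overlaps
  expect_lte(k, 10)              # almost nothing is o
  expect_gte(inspected_count(got_it), m / 2)
  expect_lte(visit_count(got_rt), 8 * (log2(n) + 1) + 2 * k)
})
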