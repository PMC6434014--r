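test_that("a single interval builds a single-leaf tree", {
  S <- genomic_intervals("chr1", 10, 20, index = 7L)
  tr <- build_rtfc(S)
  expect_length(tr$key, 1)
  expect_equal(tr$leaf[tr$root], 1L)
  expect_equal(index_leaves(tr)$index, 7L)
  expect_equal(as.integer(query_rtfc(tr, query_interval("chr1", 10, 20), "=")),
               7L)
  # non-matching relation on the one-leaf tree
  res <- query_rtfc(tr, query_interval("chr1", 10, 20), "o")
  expect_length(res, 0)
  expect_equal(visit_count(res), 1L)
})

test_that("the 8-interval fixture builds the documented shape", {
  fx <- adversarial_suite()$fig_walkthrough
  tr <- build_rtfc(fx)
  xs <- sort(fx$start)
  expect_equal(tree_height(tr), 3L)
  root <- tr$root
  expect_equal(tr$key[root], xs[4])                       # rank 4
  lv1 <- c(tr$left[root], tr$right[root])
  expect_equal(tr$key[lv1], xs[c(2, 6)])                  # ranks 2, 6
  lv2 <- c(tr$left[lv1], tr$right[lv1])[c(1, 3, 2, 4)]
  expect_equal(sort(tr$key[lv2]), xs[c(1, 3, 5, 7)])      # ranks 1, 3, 5, 7
})

test_that("the walkthrough d-query on [2,10] returns its 4 intervals", {
  fx <- adversarial_suite()$fig_walkthrough
  tr <- build_rtfc(fx)
  q <- query_interval("chrA", 2, 10)
  # the x-paths split at the root (the node keyed at rank 4)
  box <- allen_rewrite("d", q)
  expect_equal(find_split_node(tr, box$x_low, box$x_high), tr$root)
  res <- query_rtfc(tr, q, "d")
  expect_equal(as.integer(res), c(2L, 3L, 4L, 6L))
  expect_same_ids(res, brute_interval_query(fx, q, "d"))
})

test_that("leaves read left-to-right are S sorted by (start, index)", {
  for (seed in 1:5) {
    S <- generate_uniform(sample(2:200, 1), 30, seed = seed)
    tr <- build_rtfc(S)
    ord <- order(S$start, S$index)
    leaves <- index_leaves(tr)
    expect_equal(leaves$start, S$start[ord])
    expect_equal(leaves$end, S$end[ord])
    expect_equal(leaves$index, S$index[ord])
  }
})

test_that("split node equals the last common node of the two descent paths", {
  set.seed(31)
  for (k in 1:20) {
    S <- generate_uniform(sample(2:300, 1), 40, seed = 300 + k)
    tr <- build_rtfc(S)
    x1 <- sample(0:45, 1)
    x2 <- x1 + sample(0:10, 1)
    expect_equal(find_split_node(tr, x1, x2), split_node_oracle(tr, x1, x2))
  }
  # both descents ending on the same leaf yield that leaf
  S <- generate_uniform(64, 1000, seed = 77)
  tr <- build_rtfc(S)
  x <- tr$x[5]
  v <- find_split_node(tr, x, x)
  expect_equal(v, split_node_oracle(tr, x, x))
})

test_that("rtfc agrees with the oracle across relations and instances", {
  for (k in 1:30) {
    inst <- random_instance(seed = 500 + k, n = sample(16:512, 1))
    tr <- build_rtfc(inst$S)
    for (r in allen_relations()) {
      expect_same_ids(query_rtfc(tr, inst$q, r),
                      brute_interval_query(inst$S, inst$q, r))
    }
  }
})

test_that("adversarial fixtures are answered exactly", {
  for (fx in adversarial_suite()) {
    tr <- build_rtfc(fx)
    qs <- rbind(fx[1, ], fx[nrow(fx), ])
    qs <- genomic_intervals(qs$chrom, qs$start, qs$end, seq_len(2))
    for (i in 1:2) {
      q <- qs[i, , drop = FALSE]
      for (r in allen_relations()) {
        expect_same_ids(query_rtfc(tr, q, r),
                        brute_interval_query(fx, q, r))
      }
    }
  }
  # duplicate faithfulness: every copy reported exactly once
  ident <- adversarial_suite()$identical
  tr <- build_rtfc(ident)
  res <- query_rtfc(tr, query_interval("chrA", 100, 200), "=")
  expect_equal(as.integer(res), sort(ident$index))
})

test_that("node data arrays are exact y-sorted merges with sound FC links", {
  S <- generate_uniform(777, 200, seed = 13)  # heavy coordinate duplication
  tr <- build_rtfc(S)
  expect_equal(rtfc_check_merge(tr), 0L)
  set.seed(99)
  expect_equal(rtfc_check_fc(tr, c(-1, 0, 250, sample(0:220, 60))), 0L)
  # stored FC arrays match the reference constructor at a sampled node
  internal <- which(tr$leaf == 0L)
  v <- internal[length(internal) %/% 2L]
  at <- seq.int(tr$off[v], length.out = tr$len[v])
  parent_y <- tr$y[tr$pool_rank[at]]
  child_y <- function(c) tr$y[tr$pool_rank[seq.int(tr$off[c], length.out = tr$len[c])]]
  expect_equal(tr$pool_lfc[at], make_fc_index(parent_y, child_y(tr$left[v])))
  expect_equal(tr$pool_rfc[at], make_fc_index(parent_y, child_y(tr$right[v])))
})

test_that("empty-result visit counts stay logarithmic", {
  set.seed(55)
  for (n in c(256, 1024, 4096)) {
    # all data ends sit far above every query window, so k = 0 while the
    # x-range still spans about half the tree
    starts <- sample.int(1e6, n, replace = TRUE)
    S <- genomic_intervals("chrV", starts, starts + 1e6, seq_len(n))
    tr <- build_rtfc(S)
    for (k in 1:10) {
      q <- query_interval("chrV", 0, sample.int(9e5, 1) + 2)
      res <- query_rtfc(tr, q, "d")
      expect_length(res, 0)
      expect_lte(visit_count(res), 8 * (log2(n) + 1))
    }
  }
})
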