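# shared test helpers: exhaustive enumerations, random instances, oracles

# all valid closed integer intervals with endpoints in 0..N (start < end)
enumerate_intervals <- function(N, chrom = "chrT") {
  g <- expand.grid(start = 0:N, end = 0:N)
  g <- g[g$start < g$end, ]
  genomic_intervals(chrom, g$start, g$end, index = seq_len(nrow(g)))
}

# a random data set / query pair with duplicated coordinates
random_instance <- function(seed, n = NULL, coord_max = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(16:2048, 1)
  if (is.null(coord_max)) coord_max <- sample(c(50, 500, 10000), 1)
  S <- generate_uniform(n, coord_max, seed = seed + 1)
  q <- generate_queries(S, 1, seed = seed + 2)
  list(S = S, q = q)
}

expect_same_ids <- function(got, want) {
  expect_equal(as.integer(got), as.integer(want))
}

# independent descent-path oracle over the flattened x-tree arrays
descent_path <- function(tree, x, strict) {
  v <- tree$root
  path <- v
  while (tree$leaf[v] == 0L) {
    go_left <- if (strict) x < tree$key[v] else x <= tree$key[v]
    v <- if (go_left) tree$left[v] else tree$right[v]
    path <- c(path, v)
  }
  path
}

split_node_oracle <- function(tree, x1, x2) {
  p1 <- descent_path(tree, x1, strict = FALSE)
  p2 <- descent_path(tree, x2, strict = TRUE)
  common <- min(length(p1), length(p2))
  agree <- which(p1[seq_len(common)] == p2[seq_len(common)])
  p1[max(agree)]
}

tree_height <- function(tree) {
  depth_of <- function(v) {
    if (tree$leaf[v] > 0L) return(0L)
    1L + max(depth_of(tree$left[v]), depth_of(tree$right[v]))
  }
  depth_of(tree$root)
}
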