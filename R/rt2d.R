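#' Build a basic 2-dimensional range tree
#'
#' Baseline structure: the same balanced x-tree as [build_rtfc()] (identical
#' split rules, so the two trees always share their shape), but instead of
#' fractional-cascading indices each node carries a flattened 1-D search
#' structure over the `end` values of its subtree — a sorted array queried
#' by binary search, behaviourally a static balanced BST. Queries decompose
#' the x-range into O(log n) canonical subtrees and run an independent 1-D
#' y-search in each, giving O(log^2 n + k) per query.
#'
#' @param S a non-empty `genomic_intervals` set on one chromosome.
#' @return An object of class `rt2d_index`.
#' @export
build_rt2d <- function(S) {
  build_xtree(S, with_fc = FALSE, class = "rt2d_index")
}

#' Query a 2D-RT index for one Allen relation
#'
#' Canonical-subtree decomposition on x followed by a binary search for the
#' lower y-bound in each canonical node's y-array. In the visit counter
#' each binary-search halving step counts as one visit (one node of the
#' flattened y-tree), so the counter exhibits the structure's
#' O(log^2 n + k) behaviour.
#'
#' @inheritParams query_rtfc
#' @param tree an `rt2d_index` from [build_rt2d()].
#' @return Sorted integer vector of provenance indices with `visits` and
#'   `reported` attributes; always identical to [query_rtfc()] and to the
#'   brute-force oracle on the same input.
#' @export
query_rt2d <- function(tree, q, r) {
  stopifnot(inherits(tree, "rt2d_index"))
  b <- query_bounds(tree, q, r)
  ans <- cpp_query_rt2d(tree, b[1L], b[2L], b[3L], b[4L])
  with_instrumentation(ans)
}

#' Extract a node's 1-D y-structure
#'
#' @param tree an `rt2d_index` (or `rtfc_index`; the data arrays coincide).
#' @param node integer node id, e.g. from [find_split_node()].
#' @return A list with components `y` (sorted end values) and `index`
#'   (matching provenance indices), the node's flattened y-tree.
#' @export
rt2d_ytree <- function(tree, node) {
  stopifnot(inherits(tree, "allen_index"))
  if (node < 1L || node > length(tree$key)) stop("no such node")
  at <- seq.int(tree$off[node], length.out = tree$len[node])
  ranks <- tree$pool_rank[at]
  list(y = tree$y[ranks], index = tree$id[ranks])
}

#' 1-D range report on a sorted y-structure
#'
#' Reports every entry of a flattened y-tree whose value lies between two
#' bounds, via binary search on both ends (O(log m + k)).
#'
#' @param ytree a list with `y` (sorted ascending) and `index`, as returned
#'   by [rt2d_ytree()].
#' @param y_low,y_high [bound()] objects or plain numbers (closed bounds).
#' @return Sorted integer vector of provenance indices.
#' @export
query_1d <- function(ytree, y_low, y_high) {
  y <- ytree$y
  if (is.unsorted(y)) stop("ytree$y must be sorted ascending")
  lo <- effective_bound(y_low, lower = TRUE)
  hi <- effective_bound(y_high, lower = FALSE)
  if (lo > hi || !length(y)) return(integer(0))
  from <- findInterval(lo, y, left.open = TRUE) + 1L  # first y >= lo
  to <- findInterval(hi, y)                           # last y <= hi
  if (from > to) return(integer(0))
  sort(ytree$index[from:to])
}
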