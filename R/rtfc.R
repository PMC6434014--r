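#' Build a range tree with fractional cascading
#'
#' The main index structure. Intervals are mapped to 2-D points
#' `(start, end)` and stored in a static balanced binary tree on `start`:
#' intervals live in the leaves (left-to-right in `(start, index)` order)
#' and every internal node keys on the largest `start` in its left subtree.
#' Splits are at the median start value, everything equal to the median
#' going left; when all starts in a subproblem are equal, a rank split keeps
#' the two halves non-empty and the tree balanced. Each node also carries
#' its subtree's intervals as an array sorted by `(end, index)`, plus two
#' fractional-cascading index arrays giving, for every element, the
#' position of the smallest element no less than it in each child's array
#' (`-1` when no such element exists). A query then needs a single binary
#' search on `end` at the split node; positions in all deeper nodes follow
#' by constant-time index propagation, which is what brings the query cost
#' to O(log n + k).
#'
#' @param S a non-empty `genomic_intervals` set on one chromosome.
#' @return An object of class `rtfc_index`.
#' @seealso [query_rtfc()], [build_rt2d()], [build_it()]
#' @export
build_rtfc <- function(S) {
  build_xtree(S, with_fc = TRUE, class = "rtfc_index")
}

# shared x-tree constructor for rtfc / rt2d
build_xtree <- function(S, with_fc, class) {
  if (!nrow(S)) stop("cannot build an index over an empty interval set")
  chrom <- single_chrom(S)
  ord <- order(S$start, S$index)
  xs <- S$start[ord]
  ys <- S$end[ord]
  ids <- S$index[ord]
  tree <- cpp_build_tree(xs, ys, ids, with_fc)
  tree$x <- xs
  tree$y <- ys
  tree$id <- ids
  tree$n <- length(xs)
  tree$chrom <- chrom
  class(tree) <- c(class, "allen_index")
  tree
}

#' @export
print.allen_index <- function(x, ...) {
  kind <- class(x)[1L]
  cat(sprintf("%s over %d interval(s) on %s (%d tree nodes)\n",
              kind, x$n, x$chrom, length(x$key)))
  invisible(x)
}

#' Query an RTFC index for one Allen relation
#'
#' Rewrites `(r, q)` to a 2-D range query via [allen_rewrite()] and answers
#' it with one binary search at the split node followed by cascaded index
#' propagation along both descent paths. The result carries instrumentation
#' readable with [visit_count()].
#'
#' @param tree an `rtfc_index` from [build_rtfc()].
#' @param q a single query interval on the indexed chromosome.
#' @param r relation symbol (aliases accepted).
#' @return Sorted integer vector of provenance indices, with attributes
#'   `visits` (tree nodes touched, excluding per-result reporting) and
#'   `reported` (result count).
#' @export
query_rtfc <- function(tree, q, r) {
  stopifnot(inherits(tree, "rtfc_index"))
  b <- query_bounds(tree, q, r)
  ans <- cpp_query_rtfc(tree, b[1L], b[2L], b[3L], b[4L])
  with_instrumentation(ans)
}

# normalize (q, r) to effective closed bounds against an index
query_bounds <- function(tree, q, r) {
  q <- as_query(q)
  if (!identical(q$chrom, tree$chrom)) {
    warning(sprintf("query chromosome '%s' does not match index chromosome '%s'",
                    q$chrom, tree$chrom))
  }
  normalize_box(allen_rewrite(r, q))
}

with_instrumentation <- function(ans) {
  ids <- ans$ids
  attr(ids, "visits") <- ans$visits
  attr(ids, "reported") <- ans$reported
  if (!is.null(ans$inspected)) attr(ids, "inspected") <- ans$inspected
  ids
}

#' Instrumentation accessors
#'
#' Every indexed query returns its result with counters attached:
#' `visit_count()` reads the number of tree nodes touched while answering
#' (excluding per-result reporting steps); `inspected_count()` reads, for
#' interval-tree queries, the number of candidate intervals whose
#' endpoints were examined.
#'
#' @param result the return value of a query function.
#' @return A non-negative integer (or `NA` if the counter does not apply).
#' @export
visit_count <- function(result) {
  v <- attr(result, "visits")
  if (is.null(v)) NA_integer_ else v
}

#' @rdname visit_count
#' @export
inspected_count <- function(result) {
  v <- attr(result, "inspected")
  if (is.null(v)) NA_integer_ else v
}

#' Find the split node of an x-range
#'
#' Descends from the root until the search paths for the two x-bounds
#' diverge, or until a leaf is reached when both descents end there (the
#' case for degenerate ranges such as `s`, `si` and `=` queries).
#'
#' @param tree an `rtfc_index` or `rt2d_index`.
#' @param x_low,x_high [bound()] objects (or plain numbers, taken as
#'   closed bounds) with `x_low <= x_high`.
#' @return Integer node id (1-based; the root is node 1 only by
#'   coincidence of construction order — use the returned id opaquely).
#' @export
find_split_node <- function(tree, x_low, x_high) {
  stopifnot(inherits(tree, "allen_index"))
  x1 <- effective_bound(x_low, lower = TRUE)
  x2 <- effective_bound(x_high, lower = FALSE)
  if (x1 > x2) stop("x_low must not exceed x_high")
  cpp_find_split(tree, x1, x2)$node
}

effective_bound <- function(b, lower) {
  if (inherits(b, "allen_bound")) {
    if (b$closed || is.infinite(b$value)) return(b$value)
    return(if (lower) b$value + 1 else b$value - 1)
  }
  as.numeric(b)
}

#' Structural audits of an RTFC index
#'
#' `rtfc_check_merge()` verifies that every internal node's data array is
#' the exact `(end, index)`-sorted merge of its children's arrays.
#' `rtfc_check_fc()` verifies, for each probe value, that the cascaded
#' child position stored in the FC-index arrays equals an independent
#' binary search in the child's array, at every internal node.
#'
#' @param tree an `rtfc_index`.
#' @param probes numeric vector of y-values to audit with.
#' @return Number of violations (0 when the structure is sound).
#' @export
rtfc_check_merge <- function(tree) {
  stopifnot(inherits(tree, "allen_index"))
  cpp_check_merge(tree)
}

#' @rdname rtfc_check_merge
#' @export
rtfc_check_fc <- function(tree, probes) {
  stopifnot(inherits(tree, "rtfc_index"))
  cpp_fc_audit(tree, as.numeric(probes))
}

#' Leaf intervals in left-to-right order
#'
#' @param tree an `rtfc_index` or `rt2d_index`.
#' @return A `genomic_intervals` set: the indexed intervals sorted by
#'   `(start, index)`, i.e. the leaf sequence of the x-tree.
#' @export
index_leaves <- function(tree) {
  stopifnot(inherits(tree, "allen_index"))
  genomic_intervals(tree$chrom, tree$x, tree$y, tree$id)
}
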