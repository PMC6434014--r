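#' Build an augmented red-black interval tree
#'
#' Baseline structure: a red-black tree keyed on interval start (ties
#' broken by end, then provenance index, so heavily duplicated pooled data
#' is handled deterministically), with every node augmented by the maximum
#' end value in its subtree. Built by iterative insertion — a standard
#' red-black insert whose rotations also maintain the augmentation. Supports
#' the coarse overlap query in O(log n + m); refined Allen relations are
#' answered by post-filtering the m overlap candidates, which is exactly the
#' O(log n + 2m) behaviour the range trees are designed to beat when the
#' refined result size k is much smaller than m.
#'
#' @param S a `genomic_intervals` set on one chromosome (may be empty).
#' @param audit if `TRUE`, verify the red-black and max-end invariants
#'   after every single insertion (used by the structural test suite).
#' @return An object of class `it_index`. With `audit = TRUE` the attribute
#'   `audit_violations` holds the number of post-insertion states that
#'   violated an invariant (0 for a correct build).
#' @export
build_it <- function(S, audit = FALSE) {
  chrom <- if (nrow(S)) single_chrom(S) else NA_character_
  tree <- cpp_it_build(S$start, S$end, S$index, audit)
  tree$n <- nrow(S)
  tree$chrom <- chrom
  class(tree) <- c("it_index", "allen_index")
  tree
}

#' Validate interval-tree invariants
#'
#' Checks the red-black properties (black root, no red node with a red
#' child, equal black height on every root-to-nil path), the search-tree
#' order on `(start, end, index)`, parent pointers, and that every node's
#' `max_end` equals the maximum end value in its subtree.
#'
#' @param tree an `it_index`.
#' @return `TRUE` if all invariants hold.
#' @export
it_validate <- function(tree) {
  stopifnot(inherits(tree, "it_index"))
  cpp_it_validate(tree)
}

#' In-order traversal of an interval tree
#'
#' @param tree an `it_index`.
#' @return Provenance indices in key order, i.e. sorted by
#'   `(start, end, index)`.
#' @export
it_inorder <- function(tree) {
  stopifnot(inherits(tree, "it_index"))
  cpp_it_inorder(tree)
}

#' Coarse overlap query on an interval tree
#'
#' Reports every interval intersecting `q` under the closed-interval test
#' `a.start <= q.end && a.end >= q.start`, pruning subtrees whose `max_end`
#' falls short of `q.start`. This equals the union of the 11 intersecting
#' Allen relations.
#'
#' @param tree an `it_index`.
#' @param q a single query interval on the indexed chromosome.
#' @return Sorted integer vector of provenance indices with an `inspected`
#'   attribute counting candidate examinations (readable with
#'   [inspected_count()]).
#' @export
query_overlap_it <- function(tree, q) {
  stopifnot(inherits(tree, "it_index"))
  q <- as_query(q)
  it_check_chrom(tree, q)
  ans <- cpp_it_overlap(tree, q$start, q$end)
  with_instrumentation(ans)
}

it_check_chrom <- function(tree, q) {
  if (tree$n > 0L && !identical(q$chrom, tree$chrom)) {
    warning(sprintf("query chromosome '%s' does not match index chromosome '%s'",
                    q$chrom, tree$chrom))
  }
}

#' Refined Allen-relation query on an interval tree
#'
#' For the 11 intersecting relations: run the coarse overlap query, then
#' filter the m candidates with [allen_classify()] (the single source of
#' relation semantics shared with the range trees, so the structures can
#' never disagree). For `<` and `>`, where candidates do not intersect `q`,
#' an ordered traversal with subtree pruning collects them instead.
#'
#' @inheritParams query_overlap_it
#' @param r relation symbol (aliases accepted).
#' @return Sorted integer vector of provenance indices with an `inspected`
#'   attribute; always equal to [brute_interval_query()].
#' @export
query_relation_it <- function(tree, q, r) {
  stopifnot(inherits(tree, "it_index"))
  r <- as_relation(r)
  q <- as_query(q)
  it_check_chrom(tree, q)
  if (tree$n == 0L) {
    out <- integer(0)
    attr(out, "inspected") <- 0L
    return(out)
  }
  if (r == "<") {
    ans <- cpp_it_before(tree, q$start)
    ids <- with_instrumentation(ans)
    return(ids)
  }
  if (r == ">") {
    ans <- cpp_it_after(tree, q$end)
    return(with_instrumentation(ans))
  }
  cand <- query_overlap_it(tree, q)
  if (!length(cand)) return(cand)
  pos <- match(cand, tree$id)
  hits <- classify_xy(tree$start[pos], tree$end[pos], q$start, q$end) == r
  out <- sort(as.integer(cand[hits]))
  attr(out, "inspected") <- attr(cand, "inspected")
  out
}
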