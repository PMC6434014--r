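#' Brute-force interval query (reference oracle)
#'
#' Linear scan defining ground truth for every indexed query path: classify
#' every data interval against `q` and keep those whose relation is `r`.
#' O(n) per query by design; order-insensitive and duplicate-faithful
#' (intervals sharing coordinates are each reported under their own
#' provenance index).
#'
#' @param S a `genomic_intervals` set on one chromosome.
#' @param q a single query interval on the same chromosome.
#' @param r relation symbol (aliases accepted).
#' @return Sorted integer vector of provenance indices.
#' @export
brute_interval_query <- function(S, q, r) {
  r <- as_relation(r)
  if (nrow(S) == 0L) return(integer(0))
  sort(S$index[allen_classify(S, q) == r])
}

#' Brute-force 2-D range report (reference oracle)
#'
#' Reports every interval whose `(start, end)` point lies inside `box`, by
#' linear scan. When `box == allen_rewrite(r, q)` this agrees exactly with
#' [brute_interval_query()].
#'
#' @param S a `genomic_intervals` set.
#' @param box a [range_box()].
#' @return Sorted integer vector of provenance indices.
#' @export
brute_range_report <- function(S, box) {
  if (nrow(S) == 0L) return(integer(0))
  sort(S$index[point_in_box(S$start, S$end, box)])
}
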