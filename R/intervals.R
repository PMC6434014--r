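#' Construct a set of genomic intervals
#'
#' A `genomic_intervals` object is a plain data frame with columns `chrom`,
#' `start`, `end` and `index`, representing closed integer intervals
#' \eqn{[start, end]} on a chromosome. Coordinates are used verbatim as
#' closed endpoints; every interval must satisfy `start < end`, so the
#' associated 2-D point `(start, end)` lies strictly above the diagonal
#' `y = x`. The `index` column is a stable provenance id: it identifies an
#' interval through every index structure and query result, so duplicated
#' coordinates remain distinguishable.
#'
#' @param chrom character vector of chromosome names (recycled if scalar).
#' @param start,end integer genomic coordinates; `start < end` elementwise.
#' @param index optional integer provenance ids, unique within the set;
#'   defaults to `seq_along(start)`.
#' @return A data frame of class `genomic_intervals`.
#' @examples
#' genomic_intervals("chr1", c(1, 4), c(5, 9))
#' @export
genomic_intervals <- function(chrom, start, end, index = seq_along(start)) {
  if (length(start) != length(end)) {
    stop("start and end must have equal length")
  }
  chrom <- rep_len(as.character(chrom), length(start))
  start <- as.numeric(start)
  end <- as.numeric(end)
  index <- as.integer(index)
  if (anyNA(start) || anyNA(end)) stop("coordinates must be non-missing")
  if (any(start >= end)) {
    stop("invalid interval: start must be strictly less than end")
  }
  if (anyNA(index) || any(index < 0)) stop("index must be a non-negative integer")
  if (anyDuplicated(index)) stop("provenance indices must be unique")
  structure(
    data.frame(chrom = chrom, start = start, end = end, index = index,
               stringsAsFactors = FALSE),
    class = c("genomic_intervals", "data.frame")
  )
}

#' Construct a single query interval
#'
#' Convenience wrapper for a one-row [genomic_intervals()] used as the query
#' side of an interval query.
#'
#' @param chrom chromosome name.
#' @param start,end closed integer endpoints, `start < end`.
#' @return One-row `genomic_intervals`.
#' @export
query_interval <- function(chrom, start, end) {
  genomic_intervals(chrom, start, end, index = 0L)
}

#' @export
print.genomic_intervals <- function(x, ...) {
  cat(sprintf("genomic_intervals with %d interval(s) on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  NextMethod()
}

# internal: assert one chromosome and return it
single_chrom <- function(S) {
  ch <- unique(S$chrom)
  if (length(ch) != 1L) {
    stop("intervals span multiple chromosomes; split by chromosome first")
  }
  ch
}

# internal: check comparability of a data set / query pair
check_same_chrom <- function(a, q) {
  if (!all(a$chrom == q$chrom[1L])) {
    stop("incomparable pair: intervals lie on different chromosomes")
  }
  invisible(TRUE)
}

as_query <- function(q) {
  if (is.data.frame(q)) {
    if (nrow(q) != 1L) stop("query must be a single interval")
    return(q)
  }
  stop("query must be a one-row genomic_intervals")
}
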