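#' Deterministic uniform random intervals
#'
#' Draws `n` intervals with both endpoints uniform on `0..coord_max`,
#' redrawing until `start < end` (equivalently: two distinct uniform draws
#' assigned in sorted order). Reproducible for a fixed seed; the caller's
#' random-number state is left untouched.
#'
#' @param n number of intervals (>= 1).
#' @param coord_max largest coordinate value (>= 2); duplicates among
#'   endpoints are expected and welcome when `coord_max` is small
#'   relative to `n`.
#' @param seed integer seed.
#' @param chrom chromosome name for the generated set.
#' @return A `genomic_intervals` of `n` rows with indices `1..n`.
#' @export
generate_uniform <- function(n, coord_max, seed, chrom = "chrS") {
  stopifnot(n >= 1, coord_max >= 2)
  with_seed(seed, {
    a <- sample.int(coord_max + 1L, n, replace = TRUE) - 1L
    b <- sample.int(coord_max + 1L, n, replace = TRUE) - 1L
    eq <- a == b
    while (any(eq)) {
      b[eq] <- sample.int(coord_max + 1L, sum(eq), replace = TRUE) - 1L
      eq <- a == b
    }
    genomic_intervals(chrom, pmin(a, b), pmax(a, b), index = seq_len(n))
  })
}

# run code under a fixed seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Named adversarial fixtures
#'
#' Deterministic interval sets stressing the degenerate configurations the
#' index structures must handle:
#'
#' * `identical`: 20 copies of one interval (duplicate faithfulness; an
#'   `=` query must return all of them).
#' * `same_start`: 20 intervals sharing a start (degenerate x-ranges,
#'   rank-split fallback).
#' * `same_end`: 20 intervals sharing an end (y-sort ties).
#' * `nested`: a fully nested chain of depth 50 — every interior interval
#'   is `d` (during) of the outermost.
#' * `touching`: a chain of 10 abutting intervals, rich in `m`/`mi` pairs.
#' * `fig_walkthrough`: a synthetic 8-interval set, labelled
#'   "walkthrough-consistent": starts `1,3,4,5,6,7,8,9` so the x-tree
#'   splits at ranks 4; 2,6; 1,3,5,7, and ends chosen so a `d` query
#'   against `[2, 10]` returns exactly the 4 intervals with indices
#'   2, 3, 4, 6 via descent paths through ranks 4-2-1-2 and 4-6-7-8.
#'
#' @return Named list of `genomic_intervals`.
#' @export
adversarial_suite <- function() {
  list(
    identical = genomic_intervals("chrA", rep(100, 20), rep(200, 20)),
    same_start = genomic_intervals("chrA", rep(50, 20), 51 + 7 * (0:19)),
    same_end = genomic_intervals("chrA", 3 * (0:19), rep(500, 20)),
    nested = nested_chain(50),
    touching = touching_chain(10),
    fig_walkthrough = genomic_intervals(
      "chrA",
      start = c(1, 3, 4, 5, 6, 7, 8, 9),
      end   = c(12, 5, 6, 8, 11, 9, 13, 14)
    )
  )
}

#' @rdname adversarial_suite
#' @param depth number of nested intervals; interval `i` is
#'   `[i - 1, 2 * depth - i + 1]`, so each is strictly inside the previous.
#' @export
nested_chain <- function(depth) {
  i <- seq_len(depth)
  genomic_intervals("chrA", i - 1, 2 * depth - i + 1, index = i)
}

#' @rdname adversarial_suite
#' @param len number of abutting unit-10 intervals `[10(i-1), 10i]`; each
#'   meets the next.
#' @export
touching_chain <- function(len) {
  i <- seq_len(len)
  genomic_intervals("chrA", 10 * (i - 1), 10 * i, index = i)
}

#' Random query intervals matched to a data set
#'
#' Draws query intervals whose endpoints mix fresh uniform draws with
#' endpoints re-used from the data set, so equality-sensitive relations
#' (`m`, `mi`, `s`, `si`, `f`, `fi`, `=`) fire regularly rather than almost
#' never.
#'
#' @param S a `genomic_intervals` data set.
#' @param n_q number of query intervals.
#' @param seed integer seed.
#' @return A `genomic_intervals` of `n_q` rows on the same chromosome.
#' @export
generate_queries <- function(S, n_q, seed) {
  chrom <- single_chrom(S)
  cmax <- max(S$end)
  with_seed(seed, {
    pool <- c(S$start, S$end)
    pick <- function(n) {
      reuse <- stats::runif(n) < 0.5
      v <- numeric(n)
      v[reuse] <- sample(pool, sum(reuse), replace = TRUE)
      v[!reuse] <- sample.int(cmax + 1L, sum(!reuse), replace = TRUE) - 1L
      v
    }
    a <- pick(n_q)
    b <- pick(n_q)
    eq <- a == b
    while (any(eq)) {
      b[eq] <- pick(sum(eq))
      eq <- a == b
    }
    genomic_intervals(chrom, pmin(a, b), pmax(a, b), index = seq_len(n_q))
  })
}
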