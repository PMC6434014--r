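#' The 13 Allen interval relations
#'
#' Allen's interval algebra partitions all ordered pairs of valid intervals
#' (`start < end` on both sides) into 13 mutually exclusive, jointly
#' exhaustive qualitative relations. With a data interval `a = [x, y]` and a
#' query interval `q = [x', y']` the definitions are orderings of the four
#' endpoints:
#'
#' | symbol | name          | definition            |
#' |--------|---------------|-----------------------|
#' | `o`    | overlaps      | `x < x' < y < y'`     |
#' | `oi`   | overlapped-by | `x' < x < y' < y`     |
#' | `d`    | during        | `x' < x < y < y'`     |
#' | `di`   | contains      | `x < x' < y' < y`     |
#' | `m`    | meets         | `x < y = x' < y'`     |
#' | `mi`   | met-by        | `x' < y' = x < y`     |
#' | `s`    | starts        | `x = x' < y < y'`     |
#' | `si`   | started-by    | `x = x' < y' < y`     |
#' | `f`    | finishes      | `x' < x < y = y'`     |
#' | `fi`   | finished-by   | `x < x' < y' = y`     |
#' | `<`    | before        | `x < y < x' < y'`     |
#' | `>`    | after         | `x' < y' < x < y`     |
#' | `=`    | equals        | `x = x', y = y'`      |
#'
#' Eleven of the 13 (all but `<` and `>`) imply that the two intervals
#' intersect under the closed-interval test `a.start <= q.end` and
#' `a.end >= q.start`; [intersecting_relations()] returns that subset.
#'
#' @return Character vector of the 13 relation symbols.
#' @seealso [allen_classify()], [allen_rewrite()], [coarse_relation_set()]
#' @export
allen_relations <- function() {
  c("o", "oi", "d", "di", "m", "mi", "s", "si", "f", "fi", "<", ">", "=")
}

#' @rdname allen_relations
#' @export
intersecting_relations <- function() {
  c("o", "oi", "d", "di", "m", "mi", "s", "si", "f", "fi", "=")
}

# ASCII aliases accepted in files and on the command line
.relation_aliases <- c(lt = "<", gt = ">", eq = "=")

#' Normalize a relation symbol
#'
#' Accepts the 13 canonical symbols plus the ASCII aliases `lt`, `gt`, `eq`
#' for `<`, `>`, `=` (useful in file names and shells).
#'
#' @param r a relation symbol or alias.
#' @return The canonical symbol.
#' @export
as_relation <- function(r) {
  r <- as.character(r)
  if (length(r) != 1L) stop("exactly one relation symbol expected")
  if (r %in% names(.relation_aliases)) r <- .relation_aliases[[r]]
  if (!r %in% allen_relations()) {
    stop(sprintf("unknown Allen relation '%s'", r))
  }
  r
}

#' Converse of an Allen relation
#'
#' `a r q` holds if and only if `q converse(r) a` holds; the pairing is
#' `o/oi`, `d/di`, `m/mi`, `s/si`, `f/fi`, `</>` with `=` self-converse.
#'
#' @param r relation symbol (aliases accepted).
#' @return The converse symbol.
#' @export
allen_converse <- function(r) {
  r <- as_relation(r)
  conv <- c(o = "oi", oi = "o", d = "di", di = "d", m = "mi", mi = "m",
            s = "si", si = "s", f = "fi", fi = "f",
            "<" = ">", ">" = "<", "=" = "=")
  conv[[r]]
}

#' Classify the Allen relation between interval pairs
#'
#' For each data interval in `a` returns the unique Allen relation it stands
#' in to the query interval `q`. The classification is distinctive and
#' exhaustive: exactly one of the 13 symbols holds for every valid pair.
#'
#' @param a a `genomic_intervals` set (vectorized over rows).
#' @param q a single query interval on the same chromosome.
#' @return Character vector of relation symbols, one per row of `a`.
#' @examples
#' a <- genomic_intervals("chr1", 1, 3)
#' q <- query_interval("chr1", 2, 5)
#' allen_classify(a, q)  # "o"
#' @export
allen_classify <- function(a, q) {
  q <- as_query(q)
  check_same_chrom(a, q)
  classify_xy(a$start, a$end, q$start, q$end)
}

# vectorized endpoint-order classification; x < y and qx < qy assumed
classify_xy <- function(x, y, qx, qy) {
  r <- character(length(x))
  r[y < qx] <- "<"
  r[x > qy] <- ">"
  r[y == qx] <- "m"
  r[x == qy] <- "mi"
  rest <- r == ""
  sx <- sign(x - qx)
  sy <- sign(y - qy)
  r[rest & sx < 0 & sy < 0] <- "o"
  r[rest & sx < 0 & sy == 0] <- "fi"
  r[rest & sx < 0 & sy > 0] <- "di"
  r[rest & sx == 0 & sy < 0] <- "s"
  r[rest & sx == 0 & sy == 0] <- "="
  r[rest & sx == 0 & sy > 0] <- "si"
  r[rest & sx > 0 & sy < 0] <- "d"
  r[rest & sx > 0 & sy == 0] <- "f"
  r[rest & sx > 0 & sy > 0] <- "oi"
  r
}

#' Does a specific Allen relation hold?
#'
#' @param a a `genomic_intervals` set (vectorized over rows).
#' @param q a single query interval on the same chromosome.
#' @param r relation symbol (aliases accepted).
#' @return Logical vector: `allen_classify(a, q) == r`. This is always
#'   equivalent to membership of the point `(a$start, a$end)` in
#'   `allen_rewrite(r, q)`.
#' @export
relation_holds <- function(a, q, r) {
  allen_classify(a, q) == as_relation(r)
}

#' Coarse query types and their refined relation sets
#'
#' Overlap-finding tools expose coarse query types; each corresponds to a
#' union of refined Allen relations: `any` is the 11-member intersecting
#' set, `within` is `{d, s, f, =}`, `start` is `{s, si, =}`, `end` is
#' `{f, fi, =}` and `equal` is `{=}`. A coarse query is answered exactly by
#' taking the union of the single-relation queries in its set.
#'
#' @param type one of `"any"`, `"within"`, `"start"`, `"end"`, `"equal"`.
#' @return Character vector of refined relation symbols.
#' @export
coarse_relation_set <- function(type) {
  switch(as.character(type)[1L],
    any = intersecting_relations(),
    within = c("d", "s", "f", "="),
    start = c("s", "si", "="),
    end = c("f", "fi", "="),
    equal = "=",
    stop(sprintf("unknown coarse query type '%s'", type))
  )
}

#' Names of the coarse query types
#' @return Character vector of the five coarse type names.
#' @rdname coarse_relation_set
#' @export
coarse_types <- function() c("any", "within", "start", "end", "equal")

## ---- bounds and range boxes -------------------------------------------

#' One side of a 2-D range constraint
#'
#' An extended-integer bound: a finite value with an open/closed flag, or an
#' infinite value (always open). Strict inequalities from the relation
#' definitions become open bounds; equality constraints become closed
#' bounds. On integer coordinates an open bound `(v` admits the same points
#' as the closed bound `[v+1`, which is how the engines realize "shrink the
#' query by half a unit" without leaving integer arithmetic.
#'
#' @param value numeric scalar; may be `-Inf` or `Inf`.
#' @param closed logical; whether the endpoint itself is admitted. Must be
#'   `FALSE` for infinite values.
#' @return An object of class `allen_bound`.
#' @export
bound <- function(value, closed = FALSE) {
  value <- as.numeric(value)
  if (length(value) != 1L || is.na(value)) stop("bound value must be a scalar")
  closed <- isTRUE(closed)
  if (is.infinite(value) && closed) stop("infinite bounds must be open")
  structure(list(value = value, closed = closed), class = "allen_bound")
}

#' @export
print.allen_bound <- function(x, ...) {
  cat(sprintf("%s%s%s\n", if (x$closed) "[" else "(", x$value,
              if (x$closed) "]" else ")"))
  invisible(x)
}

#' An axis-aligned 2-D query rectangle
#'
#' The rewritten form of an interval query: interval `a` satisfies relation
#' `r` to query `q` exactly when the point `(a$start, a$end)` lies inside
#' the box [allen_rewrite()] produces. Sides are independently open, closed
#' or unbounded.
#'
#' @param x_low,x_high,y_low,y_high [bound()] objects, low <= high per axis.
#' @return An object of class `range_box`.
#' @export
range_box <- function(x_low, x_high, y_low, y_high) {
  sides <- list(x_low = x_low, x_high = x_high,
                y_low = y_low, y_high = y_high)
  for (s in sides) {
    if (!inherits(s, "allen_bound")) stop("all sides must be bound() objects")
  }
  if (x_low$value > x_high$value || y_low$value > y_high$value) {
    stop("lower bound exceeds upper bound")
  }
  structure(sides, class = "range_box")
}

#' @export
print.range_box <- function(x, ...) {
  side <- function(lo, hi) {
    sprintf("%s%s, %s%s", if (lo$closed) "[" else "(", lo$value,
            hi$value, if (hi$closed) "]" else ")")
  }
  cat(sprintf("range_box: x in %s, y in %s\n",
              side(x$x_low, x$x_high), side(x$y_low, x$y_high)))
  invisible(x)
}

# internal: collapse a box to effective closed integer bounds
# c(x1, x2, y1, y2), possibly +-Inf; empty boxes yield x1 > x2 or y1 > y2
normalize_box <- function(box) {
  lo <- function(b) if (b$closed || is.infinite(b$value)) b$value else b$value + 1
  hi <- function(b) if (b$closed || is.infinite(b$value)) b$value else b$value - 1
  c(lo(box$x_low), hi(box$x_high), lo(box$y_low), hi(box$y_high))
}

#' Point-in-box membership
#'
#' @param x,y numeric vectors of point coordinates.
#' @param box a [range_box()].
#' @return Logical vector.
#' @export
point_in_box <- function(x, y, box) {
  test <- function(v, b, lower) {
    if (is.infinite(b$value)) return(rep(TRUE, length(v)))
    if (lower) { if (b$closed) v >= b$value else v > b$value }
    else       { if (b$closed) v <= b$value else v < b$value }
  }
  test(x, box$x_low, TRUE) & test(x, box$x_high, FALSE) &
    test(y, box$y_low, TRUE) & test(y, box$y_high, FALSE)
}

#' Rewrite an interval query as a 2-D range query
#'
#' Maps `(r, q)` with `q = [x', y']` to the axis-aligned rectangle containing
#' exactly the points `(start, end)` of the intervals satisfying `a r q`:
#'
#' * `o`:  `x < x'`, `x' < y < y'`
#' * `oi`: `x' < x < y'`, `y > y'`
#' * `d`:  `x' < x < y'`, `x' < y < y'`
#' * `di`: `x < x'`, `y > y'`
#' * `m`:  `x < x'`, `y = x'`
#' * `mi`: `x = y'`, `y > y'`
#' * `s`:  `x = x'`, `x' < y < y'`
#' * `si`: `x = x'`, `y > y'`
#' * `f`:  `x' < x < y'`, `y = y'`
#' * `fi`: `x < x'`, `y = y'`
#' * `<`:  `x < x'`, `y < x'`
#' * `>`:  `x > y'`, `y > y'`
#' * `=`:  `x = x'`, `y = y'`
#'
#' Strict inequalities become open bounds, equalities closed degenerate
#' bounds, and sides with no constraint are unbounded. Lower constraints of
#' the form `0 < x` are represented as "no lower bound" rather than `x > 0`,
#' so intervals legitimately starting at coordinate 0 are never dropped.
#'
#' @param r relation symbol (aliases accepted).
#' @param q a single query interval.
#' @return A [range_box()].
#' @examples
#' allen_rewrite("d", query_interval("chr1", 2, 10))
#' @export
allen_rewrite <- function(r, q) {
  r <- as_relation(r)
  q <- as_query(q)
  xq <- q$start
  yq <- q$end
  op <- function(v) bound(v, closed = FALSE)
  cl <- function(v) bound(v, closed = TRUE)
  ninf <- bound(-Inf)
  pinf <- bound(Inf)
  switch(r,
    "o"  = range_box(ninf, op(xq), op(xq), op(yq)),
    "oi" = range_box(op(xq), op(yq), op(yq), pinf),
    "d"  = range_box(op(xq), op(yq), op(xq), op(yq)),
    "di" = range_box(ninf, op(xq), op(yq), pinf),
    "m"  = range_box(ninf, op(xq), cl(xq), cl(xq)),
    "mi" = range_box(cl(yq), cl(yq), op(yq), pinf),
    "s"  = range_box(cl(xq), cl(xq), op(xq), op(yq)),
    "si" = range_box(cl(xq), cl(xq), op(yq), pinf),
    "f"  = range_box(op(xq), op(yq), cl(yq), cl(yq)),
    "fi" = range_box(ninf, op(xq), cl(yq), cl(yq)),
    "<"  = range_box(ninf, op(xq), ninf, op(xq)),
    ">"  = range_box(op(yq), pinf, op(yq), pinf),
    "="  = range_box(cl(xq), cl(xq), cl(yq), cl(yq))
  )
}
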