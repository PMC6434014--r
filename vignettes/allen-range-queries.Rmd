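---
title: "Refined interval queries via range trees with fractional cascading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Refined interval queries via range trees with fractional cascading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allenrange)
```

## The problem

Genomic annotation routinely asks: given a large set `S` of data intervals
and a query interval `q`, which members of `S` stand in a particular
positional relation to `q`? Overlap-finding tools answer the coarse
question "which intervals intersect `q`?", but many analyses care about the
*refined* relation — an interval strictly inside a promoter window is a
different biological statement from one merely touching its edge. Allen's
interval algebra makes this precise: every ordered pair of valid intervals
(`start < end` on both sides) stands in exactly one of 13 mutually
exclusive relations, each an ordering of the four endpoints. Writing a data
interval `a = [x, y]` and query `q = [x', y']`:

| symbol | relation | definition |
|---|---|---|
| `o` / `oi` | overlaps / overlapped-by | `x < x' < y < y'` / `x' < x < y' < y` |
| `d` / `di` | during / contains        | `x' < x < y < y'` / `x < x' < y' < y` |
| `m` / `mi` | meets / met-by           | `y = x'` / `x = y'` |
| `s` / `si` | starts / started-by      | `x = x', y < y'` / `x = x', y > y'` |
| `f` / `fi` | finishes / finished-by   | `y = y', x > x'` / `y = y', x < x'` |
| `<` / `>`  | before / after           | `y < x'` / `x > y'` |
| `=`        | equals                   | `x = x', y = y'` |

Eleven of the 13 (all but `<` and `>`) coincide exactly with the
closed-interval overlap test `a.start <= q.end && a.end >= q.start`.

The difficulty is efficiency. An interval tree retrieves the `m` intervals
overlapping `q` in `O(log n + m)`, but a refined query must then inspect
all `m` candidates to keep the `k` that satisfy the refined relation —
`O(log n + 2m)` even when `k` is tiny. The structures in this package reach
`O(log n + k)` for every relation.

## Query rewriting

Map each interval `[x, y]` to the 2-D point `(x, y)`. Because `x < y`,
every point lies strictly above the diagonal — which is why zero-length
records are rejected at ingest rather than indexed. Each relation's
endpoint ordering then becomes an axis-aligned rectangle in the plane:
"find all `a` with `a r q`" is exactly "report the points of `S` inside the
rectangle `allen_rewrite(r, q)`". For example a `d` (during) query against
`[2, 10]` becomes `x in (2, 10), y in (2, 10)`:

```{r}
allen_rewrite("d", query_interval("chr1", 2, 10))
```

Two representation choices matter here:

* **Open bounds, not half-integers.** Strict inequalities are carried as
  open `bound()` flags. On integer coordinates the open bound `(2` admits
  the same set as the closed bound `[3`, so the engines normalize every
  side to a closed integer (or infinite) bound before searching — exact
  arithmetic, no floating-point half-unit shifts.
* **"0 < x" means unbounded.** Several relations constrain `x` only from
  above; the lower side is represented as unbounded rather than `x > 0`,
  since genomic coordinates may legitimately be 0 and such intervals must
  not be silently dropped.

The full `<` and `>` queries rewrite to half-unbounded rectangles and are
supported as such; in practice one usually wants only hits within `l`
bases, and `allen_flank()` provides that form as a `d` query against
`[x'-l, x']` (upstream) or `[y', y'+l]` (downstream).

## The three index structures

**RTFC** (`build_rtfc()` / `query_rtfc()`) — the primary structure. A
static balanced tree on `start`: intervals sit in the leaves in
`(start, index)` order and every internal node keys on the largest start in
its left subtree. Each node stores its subtree's intervals as an array
sorted by `(end, index)`, plus two fractional-cascading index arrays
holding, for each element, the position of the smallest element no less
than it in each child's array (`make_fc_index()`; `-1` = no successor). A
query finds the split node where the two `x`-descents diverge, performs
*one* binary search for the lower `y`-bound there, and propagates the
position to every deeper node in constant time, reporting maximal runs
terminated by the upper `y`-bound: `O(log n + k)`.

**2D-RT** (`build_rt2d()` / `query_rt2d()`) — the classical baseline. Same
x-tree; instead of FC arrays each node answers a 1-D range query on its own
y-array by independent binary search. The canonical decomposition touches
`O(log n)` nodes and each pays `O(log n)`: `O(log^2 n + k)`.

**IT** (`build_it()` / `query_relation_it()`) — the conventional baseline:
a red-black tree keyed on `(start, end, index)`, augmented with each
subtree's maximum end, built by iterative insertion (the augmentation is
maintained through the rotations). Overlap queries prune on `max_end`;
refined relations post-filter the `m` candidates through
`allen_classify()` — the same classifier used everywhere, so the
structures cannot disagree about semantics; `<`/`>` use ordered traversals
with subtree pruning instead, since their results do not overlap `q`.

A linear-scan oracle (`brute_interval_query()`, `brute_range_report()`)
defines ground truth; every indexed path is tested against it, and
`allen_compare()` runs all three structures plus the oracle over a data/
query pair and certifies agreement.

## Numerical and structural choices

* **Median split with duplicates.** Building splits at the median start
  value, all elements equal to the median going left. When every start in
  a subproblem is equal this would leave the right side empty, so the
  builder falls back to a rank split (first half left), guaranteeing
  strictly smaller subproblems and a balanced tree.
* **Degenerate x-ranges and duplicates.** `s`, `si`, `mi` and `=` queries
  constrain `x` to a single value. The descent for the upper x-bound uses
  the strict comparison "left iff `x2 < key`" (composite-key semantics), so
  when many intervals share that start the two paths still diverge at the
  node keyed on it and every duplicate is reported, each under its own
  provenance index. With no duplicates both descents end on one leaf and
  the query is essentially a binary search.
* **Deterministic ties.** y-arrays sort by `(end, index)` and the interval
  tree inserts by `(start, end, index)`, fixed at build time, so data
  arrays, FC indices and result orderings are reproducible bit for bit.
* **FC with tied ends.** FC entries compare end values only ("smallest
  element no less than"), which keeps cascaded positions equal to an
  independent binary search at every node — `rtfc_check_fc()` audits
  exactly this, and `rtfc_check_merge()` verifies each internal node's
  array is the exact sorted merge of its children.
* **Coordinates as closed integers.** BED `chromStart`/`chromEnd` values
  are used verbatim as closed endpoints by default, matching the upstream
  protocol this engine reproduces; `half_open = TRUE` converts `[s, e)` to
  `[s, e-1]` at ingest for users who want strict BED semantics. Chromosome
  names are matched as exact strings — no `chr` normalization — and
  queries on chromosomes absent from an index warn rather than fail.
* **Static indexes.** All three structures are build-once/query-many; the
  flattened arrays serialize to a versioned archive (`allen_build()`), and
  a reloaded archive answers queries bit-identically to a fresh build.
  There is no insertion or deletion support in the range trees.

## Instrumentation

Every query carries counters. `visit_count()` reports tree nodes touched,
excluding per-result reporting: for RTFC that is the split path, the two
descents and one touch per canonical child; for 2D-RT each binary-search
halving step inside a canonical node's flattened y-array also counts as one
visit (a node of the conceptual y-tree), which is what makes the
`log^2 n` behaviour visible. `inspected_count()` reports how many candidate
intervals an interval-tree query examined — the quantity that grows with
`m` rather than `k`. On a fully nested fixture where everything overlaps
the query but almost nothing satisfies `o`, the interval tree inspects
essentially all `m` candidates while the RTFC count stays near
`log n + k`; the test suite asserts exactly this ordering, and fits
empty-query visit counts against `log2 n` (RTFC, constant well under 8)
and `log2(n)^2` (2D-RT) across `n = 2^8 .. 2^14`.

## What the synthetic fixtures do and do not show

`generate_uniform()` draws endpoints uniformly (pairs redrawn on
equality), `generate_queries()` mixes fresh draws with endpoints re-used
from the data so equality-sensitive relations (`m`, `s`, `f`, `=`, ...)
occur at realistic rates, and `adversarial_suite()` covers the degenerate
shapes uniform draws rarely produce: all-identical intervals, shared
starts, shared ends, a depth-50 nested chain, an abutting chain, and an
8-interval walkthrough set whose `d` query against `[2, 10]` exercises the
documented split/descent structure. Test scales are 16–2048 intervals for
randomized oracle equivalence and up to 2^14 for scaling fits — sizes at
which exhaustive and brute-force ground truth stays exact.

Uniform endpoints are *not* realistic chromatin feature geometry: real
annotation sets have heavy-tailed lengths, clustering, and strand
structure (strand-aware filtering is out of scope here). What the passing
suite certifies is correctness — agreement with an oracle whose definition
is a direct transcription of the relation table — and the structural
scaling of the algorithms; it does not certify wall-clock performance on
any particular genome-scale corpus.

## Limitations

* Two dimensions only; the recursive d-dimensional generalization is not
  implemented.
* Indexes are per-chromosome and static; pooled multi-file data must be
  concatenated (duplicates are kept and reported individually; `dedup`
  drops exact coordinate duplicates at ingest if wanted).
* `<`/`>` on the interval tree collect candidates by ordered traversal,
  so their `inspected` counters are not comparable to the overlap path.
* BED ingest reads the first three columns only; VCF or BigBed inputs
  must be converted upstream.
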