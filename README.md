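# allenrange

Refined interval queries on genomic intervals: given a set *S* of data
intervals and a query interval *q*, report every member of *S* standing in
a chosen **Allen relation** to *q* — overlaps (`o`/`oi`), during/contains
(`d`/`di`), meets (`m`/`mi`), starts (`s`/`si`), finishes (`f`/`fi`),
before/after (`<`/`>`), equals (`=`). Overlap finders answer only the
coarse union of these; `allenrange` answers each refined relation directly,
in `O(log n + k)` time per query, where `k` is the number of results rather
than the (often far larger) number `m` of mere overlaps.

For whom: anyone annotating variants or features against large interval
collections (ChIP-seq peaks, regulatory elements, score tracks) who needs
to distinguish *strictly inside* from *touching*, *upstream-within-l* from
*anywhere before*, and so on.

## The method

An interval `[x, y]` (closed, integer, `x < y`) is mapped to the 2-D point
`(x, y)`. Each of the 13 Allen relations, being an ordering of the four
endpoints of `a = [x, y]` and `q = [x', y']`, rewrites to an axis-aligned
rectangle: e.g. `a d q  ⟺  x' < x < y' and x' < y < y'`, so a *during*
query is the rectangle `x ∈ (x', y'), y ∈ (x', y')`. Interval queries
thereby become 2-D orthogonal range reporting, answered three ways:

* **RTFC** — a range tree with fractional cascading: a balanced static
  tree on `start`, each node holding its subtree's intervals sorted by
  `end` plus FC-index arrays into its children; one binary search at the
  split node, constant-time position propagation below it.
  `O(log n + k)` per query — the structure this package exists for.
* **2D-RT** — the classical range tree (binary search per canonical node),
  `O(log² n + k)`, as a baseline.
* **IT** — an augmented red-black interval tree (subtree max-end), overlap
  in `O(log n + m)`, refined relations by post-filtering the `m`
  candidates — the conventional approach the range trees improve on.

A brute-force linear-scan oracle defines ground truth; the test suite
holds all three structures to exact agreement with it, relation by
relation.

## Worked example

```r
library(allenrange)

S  <- generate_uniform(5000, 100000, seed = 11, chrom = "chr1")  # data set
tr <- build_rtfc(S)
q  <- query_interval("chr1", 40000, 60000)

hits <- query_rtfc(tr, q, "d")          # strictly inside [40000, 60000]
length(hits)                            # 196
visit_count(hits)                       # 37  (tree nodes touched)
head(as.integer(hits))                  # 58 64 73 128 130 134

it   <- build_it(S)
cand <- query_overlap_it(it, q)         # coarse overlap on the baseline
length(cand)                            # 3400 = m: overlap candidates
inspected_count(cand)                   # 3806 intervals examined
```

196 intervals are strictly *during* the query, found after touching 37
tree nodes; the conventional interval-tree route would inspect all 3400
overlap candidates to filter out those same 196. The returned integers are
provenance indices into `S`, so duplicated coordinates remain
distinguishable.

Cross-structure consistency is a one-liner:

```r
rep <- allen_compare(list(chr1 = S[1:400, ]),
                     list(chr1 = generate_queries(S, 3, seed = 2)))
#> all structures agree with the oracle on 33 checks
#> mean visit counts per relation:
#>  relation      rtfc      rt2d       it
#>         d 25.333333 53.333333 286.3333
#>         o 27.000000 56.333333 286.3333
#>         s 10.000000 10.000000 286.3333
#>  ...
```

BED-file workflows go through `read_bed()` / `allen_build()` /
`allen_query()` / `allen_flank()`, or the installed command-line front
end:

```sh
allenrange build --data peaks.bed --structure rtfc --out peaks.rds
allenrange query --index peaks.rds --queries variants.bed --relation d --out hits.tsv
allenrange flank --index peaks.rds --queries genes.bed --side upstream --l 2000
```

See the vignette (`vignettes/allen-range-queries.Rmd`) for the model, the
tie-breaking and bound-normalization rules, and the instrumentation
semantics.

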