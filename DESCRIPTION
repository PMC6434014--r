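Package: allenrange
Title: Allen Interval Queries on Genomic Intervals via Range Trees with
    Fractional Cascading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Answers refined interval queries on genomic intervals: given a
    set of data intervals and a query interval, report every data interval
    standing in a chosen Allen relation (overlaps, during, meets, starts,
    finishes, their inverses, before, after, equals) to the query. Each of
    the 13 Allen relations is rewritten as a 2-dimensional orthogonal range
    query over the (start, end) point of an interval, and answered with a
    static range tree with fractional cascading in O(log n + k) time per
    query. A basic 2-dimensional range tree and an augmented red-black
    interval tree are provided as interchangeable baselines, and a linear
    scan oracle defines ground truth for every query path. Includes BED
    ingest, deterministic synthetic fixtures, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
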