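#' Read genomic intervals from a BED file
#'
#' Parses the first three tab-separated columns (`chrom`, `chromStart`,
#' `chromEnd`) of a BED file, transparently handling gzip compression, and
#' returns the intervals grouped by chromosome. Header lines
#' (`track`, `browser`, `#`) and blank lines are skipped; extra columns are
#' ignored. Coordinates are used verbatim as closed endpoints by default;
#' `half_open = TRUE` converts conventional half-open records `[s, e)` to
#' the closed interval `[s, e-1]` at ingest. Records whose start is not
#' strictly less than their end are invalid as intervals (their 2-D point
#' would not lie above the diagonal) and are dropped with a warning; the
#' count is available as the `dropped` attribute. Coordinates are parsed as
#' exact integers — a non-numeric coordinate raises an error naming the
#' offending line.
#'
#' @param path path to a BED (or BED.gz) file.
#' @param half_open convert `[start, end)` records to closed `[start, end-1]`.
#' @param dedup drop records duplicating an earlier `(chrom, start, end)`.
#' @return Named list, one `genomic_intervals` per chromosome, each with
#'   file-order provenance indices `1..n` within its chromosome. Attributes:
#'   `dropped` (invalid records removed) and `deduped` (duplicates removed,
#'   when `dedup = TRUE`).
#' @export
read_bed <- function(path, half_open = FALSE, dedup = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path))
  con <- gzfile(path, "rt")  # reads plain text transparently too
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  if (!length(lines)) {
    out <- list()
    attr(out, "dropped") <- 0L
    return(out)
  }
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop(sprintf("line %d: fewer than 3 tab-separated fields",
                 lineno[which(nf < 3L)[1L]]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  s_raw <- vapply(fields, `[[`, "", 2L)
  e_raw <- vapply(fields, `[[`, "", 3L)
  start <- suppressWarnings(as.numeric(s_raw))
  end <- suppressWarnings(as.numeric(e_raw))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad)) {
    stop(sprintf("line %d: malformed coordinate fields '%s', '%s'",
                 lineno[which(bad)[1L]], s_raw[which(bad)[1L]],
                 e_raw[which(bad)[1L]]))
  }
  if (half_open) end <- end - 1
  invalid <- start >= end
  dropped <- sum(invalid)
  if (dropped) {
    warning(sprintf("dropped %d record(s) with start >= end", dropped))
    chrom <- chrom[!invalid]; start <- start[!invalid]; end <- end[!invalid]
  }
  deduped <- 0L
  if (dedup) {
    dup <- duplicated(paste(chrom, start, end, sep = "\r"))
    deduped <- sum(dup)
    chrom <- chrom[!dup]; start <- start[!dup]; end <- end[!dup]
  }
  out <- lapply(split(seq_along(chrom), chrom), function(i) {
    genomic_intervals(chrom[i][1L], start[i], end[i], index = seq_along(i))
  })
  out <- out[order(names(out))]
  attr(out, "dropped") <- as.integer(dropped)
  if (dedup) attr(out, "deduped") <- deduped
  out
}

#' Write query results as tab-separated lines
#'
#' Emits one 8-field line per (query, hit) pair: query chromosome, start,
#' end, the refined relation symbol, then the data interval's chromosome,
#' start, end and provenance index. Rows are written in deterministic
#' order: query order first, then data index.
#'
#' @param records a data frame as produced by [allen_query()] /
#'   [allen_flank()], with columns `q_chrom`, `q_start`, `q_end`,
#'   `relation`, `chrom`, `start`, `end`, `index`.
#' @param file a filename or connection; `""` writes to standard output.
#' @return Invisibly, the number of lines written.
#' @export
write_results <- function(records, file = "") {
  cols <- c("q_chrom", "q_start", "q_end", "relation",
            "chrom", "start", "end", "index")
  if (!all(cols %in% names(records))) {
    stop("records must have columns ", paste(cols, collapse = ", "))
  }
  df <- records[, cols]
  utils::write.table(df, file = file, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(df))
}

#' Write intervals as a minimal 3-column BED file
#'
#' @param sets a `genomic_intervals` or a list of them (as from
#'   [read_bed()]).
#' @param path output filename.
#' @return Invisibly, the number of records written.
#' @export
write_bed <- function(sets, path) {
  if (is.data.frame(sets)) sets <- list(sets)
  df <- do.call(rbind, lapply(sets, function(s) s[, c("chrom", "start", "end")]))
  utils::write.table(df, file = path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(nrow(df))
}
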