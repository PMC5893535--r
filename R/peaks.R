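#' @importFrom GenomicRanges GRanges seqnames start end width strand reduce
#'   countOverlaps findOverlaps mcols mcols<- sort
#' @importFrom IRanges IRanges overlapsAny
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom methods is
NULL

## All genomic intervals are held as GRanges (1-based, closed), the standard
## Bioconductor convention.  BED input/output is 0-based half-open and is
## converted at the reader/writer boundary.  Chromosome names are compared as
## exact strings and ordered lexicographically.

sort_intervals <- function(gr) {
  gr <- GenomicRanges::sort(
    gr,
    ignore.strand = TRUE
  )
  gr
}

as_sorted_granges <- function(chrom, start1, end1, name = NULL,
                              strand = NULL) {
  lev <- sort(unique(chrom))
  gr <- GenomicRanges::GRanges(
    seqnames = factor(chrom, levels = lev),
    ranges = IRanges::IRanges(start = start1, end = end1),
    strand = if (is.null(strand)) "*" else strand
  )
  if (!is.null(name)) gr$name <- name
  sort_intervals(gr)
}

#' Read genomic intervals from a BED or narrowPeak file
#'
#' Parses a BED3+/BED6/narrowPeak file (optionally gzip-compressed) into a
#' sorted `GRanges`.  Input coordinates are 0-based half-open and are
#' converted to the 1-based closed convention used internally.  Columns
#' beyond the name and strand fields (e.g. narrowPeak statistics) are
#' ignored.  Duplicate intervals (same chromosome, start and end) are
#' collapsed to one.
#'
#' @param path Path to the file.  `track`/`browser`/`#` header lines and
#'   empty lines are skipped.
#' @return A `GRanges` sorted by (chromosome, start, end), with a `name`
#'   metadata column when the input has one.
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(GenomicRanges::GRanges())
  }
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("line ", idx[which(nf < 3L)[1L]],
         ": fewer than 3 tab-separated fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(!is.finite(start0) | !is.finite(end0) |
                 start0 != floor(start0) | end0 != floor(end0))
  if (length(bad)) {
    stop("line ", idx[bad[1L]], ": non-integer coordinate")
  }
  bad <- which(end0 <= start0 | start0 < 0)
  if (length(bad)) {
    stop("line ", idx[bad[1L]], ": invalid interval (requires 0 <= start < end)")
  }
  name <- ifelse(nf >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""), NA_character_)
  strand <- ifelse(nf >= 6L, vapply(fields, function(f) f[min(6L, length(f))], "*"), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- as_sorted_granges(chrom, start0 + 1, end0,
                          name = if (any(nf >= 4L)) name else NULL,
                          strand = strand)
  dup <- duplicated(paste(GenomicRanges::seqnames(gr),
                          GenomicRanges::start(gr),
                          GenomicRanges::end(gr),
                          GenomicRanges::strand(gr)))
  gr[!dup]
}

#' Read a fragment file
#'
#' A fragment file is BED3+ with one record per sequenced fragment (the span
#' covered by both mates).  Equivalent to [read_intervals()] except that
#' duplicate records are kept: several identical fragments are distinct
#' observations.
#'
#' @param path Path to a BED3+ file (optionally gzipped).
#' @return A `GRanges` of fragments.
#' @export
read_fragments <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(GenomicRanges::GRanges())
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L)) {
    stop("line ", idx[which(nf < 3L)[1L]],
         ": fewer than 3 tab-separated fields")
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(!is.finite(start0) | !is.finite(end0) | end0 <= start0 | start0 < 0)
  if (length(bad)) stop("line ", idx[bad[1L]], ": invalid fragment record")
  as_sorted_granges(chrom, start0 + 1, end0)
}

#' Merge peaks whose proximal ends are closer than a threshold
#'
#' Unites, transitively, any run of same-chromosome intervals in which the
#' gap between consecutive intervals (next start minus previous end, in bp)
#' is strictly less than `gap_lt`.  With the default of 10 bp, two peaks
#' separated by exactly 10 bp are *not* merged.  Strand is ignored.
#'
#' @param peaks A sorted `GRanges` of peaks.
#' @param gap_lt Merge gap threshold in bp (strict: merged when gap <
#'   `gap_lt`).  Must be >= 0.
#' @return A sorted `GRanges` of merged peaks named `chrom:start-end`
#'   (0-based half-open, as written to BED).
#' @export
merge_proximal <- function(peaks, gap_lt = 10L) {
  stopifnot(is(peaks, "GRanges"))
  if (!is.numeric(gap_lt) || length(gap_lt) != 1L || gap_lt < 0) {
    stop("'gap_lt' must be a single non-negative number")
  }
  ## reduce() merges ranges separated by a gap < min.gapwidth
  out <- GenomicRanges::reduce(peaks, min.gapwidth = as.integer(gap_lt),
                               ignore.strand = TRUE)
  out <- sort_intervals(out)
  out$name <- peak_names(out)
  out
}

#' Remove peaks overlapping a blacklist
#'
#' A peak overlapping any blacklist interval by at least 1 bp is removed
#' entirely (the peak is dropped, not trimmed).
#'
#' @param peaks,blacklist Sorted `GRanges`.
#' @return The subset of `peaks` with no blacklist overlap.
#' @export
subtract_blacklist <- function(peaks, blacklist) {
  stopifnot(is(peaks, "GRanges"), is(blacklist, "GRanges"))
  if (length(blacklist) == 0L) return(peaks)
  peaks[!IRanges::overlapsAny(peaks, blacklist, ignore.strand = TRUE)]
}

#' Count fragments over peaks
#'
#' Each fragment contributes 1 to the count of every peak it overlaps by at
#' least 1 bp (so a fragment spanning two peaks is counted once in each).
#'
#' @param fragments A `GRanges` of fragments or the path to a BED3+ fragment
#'   file.
#' @param peaks A sorted `GRanges` of (non-overlapping, post-merge) peaks.
#' @return An integer vector of raw counts, one per peak.
#' @export
count_fragments <- function(fragments, peaks) {
  if (is.character(fragments)) fragments <- read_fragments(fragments)
  stopifnot(is(fragments, "GRanges"), is(peaks, "GRanges"))
  GenomicRanges::countOverlaps(peaks, fragments, ignore.strand = TRUE)
}

#' Canonical peak names
#'
#' Names peaks `chrom:start-end` with BED (0-based half-open) coordinates.
#'
#' @param peaks A `GRanges`.
#' @return A character vector.
#' @export
peak_names <- function(peaks) {
  sprintf("%s:%d-%d",
          as.character(GenomicRanges::seqnames(peaks)),
          GenomicRanges::start(peaks) - 1L,
          GenomicRanges::end(peaks))
}

#' Write intervals as BED
#'
#' Writes BED with 0-based half-open coordinates; the name column defaults
#' to `chrom:start-end`.  Extra metadata columns given in `extra` are
#' appended after the name.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param extra Optional data.frame of additional columns.
#' @return Invisibly, the path.
#' @export
write_bed <- function(gr, path, extra = NULL) {
  nm <- if (!is.null(gr$name)) gr$name else peak_names(gr)
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = nm,
    stringsAsFactors = FALSE
  )
  if (!is.null(extra)) df <- cbind(df, extra)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
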