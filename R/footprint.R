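## Tn5 insertion analysis around transcription-factor motifs.
##
## Insertions are single genomic positions (1-based internally) derived
## from the two ends of each sequenced fragment.  The Tn5 transposase
## inserts as a dimer, so the conventional correction shifts the
## plus-strand end by +4 bp and the minus-strand end by -5 bp; offsets are
## applied to the 0-based fragment boundary coordinates (start and the
## exclusive end), so a BED fragment [100, 200) with the default offsets
## yields insertions at 0-based positions 104 and 195.

#' Derive Tn5 insertion positions from fragments
#'
#' @param fragments A `GRanges` of fragments or a path to a BED3+ file.
#' @param shift_plus Offset added to the 0-based fragment start
#'   (default +4).
#' @param shift_minus Offset added to the 0-based exclusive fragment end
#'   (default -5; use -1 for the naive last covered base).
#' @return A data.frame with columns `chrom` (character) and `pos`
#'   (integer, 1-based), two rows per fragment.
#' @export
insertions_from_fragments <- function(fragments, shift_plus = 4L,
                                      shift_minus = -5L) {
  if (is.character(fragments)) fragments <- read_fragments(fragments)
  stopifnot(is(fragments, "GRanges"))
  if (length(fragments) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0)))
  }
  chrom <- as.character(GenomicRanges::seqnames(fragments))
  start0 <- GenomicRanges::start(fragments) - 1L
  end0 <- GenomicRanges::end(fragments)
  pos0 <- c(start0 + shift_plus, end0 + shift_minus)
  data.frame(chrom = rep(chrom, 2L), pos = as.integer(pos0 + 1L),
             stringsAsFactors = FALSE)
}

## Count insertions falling in [start1, end1] on one chromosome for a set
## of query windows; windows as parallel vectors.
count_insertions <- function(insertions, chrom, start1, end1) {
  n <- length(start1)
  out <- integer(n)
  by_chr <- split(insertions$pos, insertions$chrom)
  for (i in seq_len(n)) {
    pos <- by_chr[[chrom[i]]]
    if (is.null(pos)) next
    out[i] <- sum(pos >= start1[i] & pos <= end1[i])
  }
  out
}

#' Footprint occupancy score (FOS)
#'
#' For each motif occurrence the central region is the motif span (length
#' L); the left and right flanks are the 3L-bp intervals immediately
#' adjacent.  `N_C` is the insertion count in the central region and
#' `N_L`, `N_R` are one third of the flank counts (kept real-valued).  The
#' score is
#' `FOS = min(-log2((N_C + 1) / (N_L + 1)), -log2((N_C + 1) / (N_R + 1)))`;
#' larger values mean deeper central protection, 0 means no depletion
#' relative to at least one flank, negative values mean central excess.
#'
#' @param insertions Insertion data.frame from
#'   [insertions_from_fragments()].
#' @param sites A `GRanges` of motif occurrences (the width is the motif
#'   length).
#' @return A data.frame with columns `site` (name or `chrom:start-end`),
#'   `motif_id` (from the `name`/`motif_id` metadata column when present),
#'   `N_C`, `N_L`, `N_R`, `fos`.
#' @export
compute_fos <- function(insertions, sites) {
  stopifnot(is(sites, "GRanges"))
  if (length(sites) == 0L) {
    return(data.frame(site = character(0), motif_id = character(0),
                      N_C = numeric(0), N_L = numeric(0), N_R = numeric(0),
                      fos = numeric(0)))
  }
  chrom <- as.character(GenomicRanges::seqnames(sites))
  s <- GenomicRanges::start(sites)
  e <- GenomicRanges::end(sites)
  L <- GenomicRanges::width(sites)
  n_c <- count_insertions(insertions, chrom, s, e)
  n_left <- count_insertions(insertions, chrom, s - 3L * L, s - 1L)
  n_right <- count_insertions(insertions, chrom, e + 1L, e + 3L * L)
  n_l <- n_left / 3
  n_r <- n_right / 3
  fos <- pmin(-log2((n_c + 1) / (n_l + 1)), -log2((n_c + 1) / (n_r + 1)))
  motif_id <- sites$motif_id
  if (is.null(motif_id)) motif_id <- sites$name
  if (is.null(motif_id)) motif_id <- NA_character_
  data.frame(site = peak_names(sites), motif_id = motif_id,
             N_C = n_c, N_L = n_l, N_R = n_r, fos = fos,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Aggregate Tn5 insertion profile around motif centers
#'
#' Sums per-base insertion counts in a window centered on each motif
#' occurrence (minus-strand sites are positionally flipped so that all
#' sites share the motif orientation), then normalizes by the total number
#' of insertions in the flanking normalization window (by default 150 bp
#' immediately outside each edge of the 200-bp window, 300 bp in total).
#'
#' @param insertions Insertion data.frame.
#' @param sites `GRanges` of motif occurrences (>= 1).
#' @param window Width of the centered window in bp (default 200).
#' @param flank_norm Total width of the flanking normalization window in
#'   bp, split evenly on the two sides (default 300).
#' @return A list of class `insertion_profile`: `positions` (relative to
#'   the motif center), `counts` (summed insertions per position),
#'   `normalized` (`counts / flank_total`, `NA` with `norm_valid = FALSE`
#'   when the flanks contain no insertions), `per_site` (mean counts per
#'   site), `n_sites`, `flank_total`.
#' @export
profile_at_motifs <- function(insertions, sites, window = 200L,
                              flank_norm = 300L) {
  stopifnot(is(sites, "GRanges"))
  if (length(sites) == 0L) stop("need at least one site")
  half <- window %/% 2L
  rel <- seq.int(-half + 1L, half)        # e.g. -99..100 for window 200
  flank_side <- flank_norm %/% 2L
  chrom <- as.character(GenomicRanges::seqnames(sites))
  center <- (GenomicRanges::start(sites) + GenomicRanges::end(sites)) %/% 2L
  minus <- as.character(GenomicRanges::strand(sites)) == "-"
  counts <- numeric(length(rel))
  flank_total <- 0
  by_chr <- split(insertions$pos, insertions$chrom)
  for (i in seq_along(sites)) {
    pos <- by_chr[[chrom[i]]]
    if (is.null(pos)) next
    r <- pos - center[i]
    if (minus[i]) r <- 1L - r           # flip around the center
    inwin <- r >= rel[1L] & r <= rel[length(rel)]
    if (any(inwin)) {
      counts <- counts + tabulate(r[inwin] - rel[1L] + 1L,
                                  nbins = length(rel))
    }
    flank_total <- flank_total +
      sum((r >= rel[1L] - flank_side & r < rel[1L]) |
            (r > rel[length(rel)] & r <= rel[length(rel)] + flank_side))
  }
  norm_valid <- flank_total > 0
  structure(list(positions = rel, counts = counts,
                 normalized = if (norm_valid) counts / flank_total else
                   rep(NA_real_, length(rel)),
                 per_site = counts / length(sites),
                 n_sites = length(sites), flank_total = flank_total,
                 norm_valid = norm_valid),
            class = "insertion_profile")
}

#' Footprint enrichment in DARs
#'
#' For each motif, counts the regions (DARs and non-DARs) that contain at
#' least one footprinted site of that motif, and tests whether footprinted
#' regions are over-represented among DARs with an upper-tail
#' hypergeometric test: `k` footprinted DARs out of `K` footprinted regions
#' drawn from `n` DARs in a universe of `N = n + |non-DARs|` regions.
#' P-values are BH-adjusted across motifs.  To stratify (e.g.
#' gene-proximal vs distal), call on the corresponding subsets of DARs and
#' non-DARs.
#'
#' @param sites `GRanges` of footprinted motif occurrences with a
#'   `motif_id` (or `name`) metadata column.
#' @param dars,non_dars Disjoint `GRanges` region sets.
#' @return A data.frame with columns `motif_id`, `k`, `K`, `n`, `N`,
#'   `pvalue`, `fdr`.
#' @export
footprint_enrichment <- function(sites, dars, non_dars) {
  stopifnot(is(sites, "GRanges"), is(dars, "GRanges"), is(non_dars, "GRanges"))
  if (length(GenomicRanges::findOverlaps(dars, non_dars,
                                         ignore.strand = TRUE)) > 0L) {
    stop("DARs and non-DARs must be disjoint")
  }
  motif_id <- sites$motif_id
  if (is.null(motif_id)) motif_id <- sites$name
  if (is.null(motif_id)) stop("sites need a 'motif_id' or 'name' column")
  in_dar <- IRanges::overlapsAny(sites, dars, ignore.strand = TRUE)
  in_non <- IRanges::overlapsAny(sites, non_dars, ignore.strand = TRUE)
  if (any(in_dar & in_non)) {
    stop("a footprint site overlaps both a DAR and a non-DAR")
  }
  n <- length(dars)
  N <- n + length(non_dars)
  motifs <- sort(unique(motif_id))
  rows <- lapply(motifs, function(m) {
    msites <- sites[motif_id == m]
    k <- sum(IRanges::overlapsAny(dars, msites, ignore.strand = TRUE))
    k_non <- sum(IRanges::overlapsAny(non_dars, msites, ignore.strand = TRUE))
    K <- k + k_non
    p <- if (K == 0L) 1 else
      stats::phyper(k - 1L, n, N - n, K, lower.tail = FALSE)
    data.frame(motif_id = m, k = k, K = K, n = n, N = N, pvalue = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_adjust(out$pvalue)
  out
}

#' Read motif occurrences from BED6
#'
#' The name field carries the motif identity; the interval width is the
#' motif length.
#'
#' @param path Path to a BED6 file.
#' @return A `GRanges` with a `motif_id` metadata column.
#' @export
read_motifs <- function(path) {
  gr <- read_intervals(path)
  if (is.null(gr$name)) stop("motif BED needs a name (motif id) column")
  gr$motif_id <- gr$name
  gr
}

#' Write FOS results as TSV
#' @param fos A data.frame from [compute_fos()].
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_fos_tsv <- function(fos, path) {
  utils::write.table(fos, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
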