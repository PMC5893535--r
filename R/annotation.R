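## Peak-to-gene annotation and GWAS SNP overlap.
##
## Gene models carry a gene body interval plus TSS/TES and, when exon
## structure is known (BED12 input), exon and UTR intervals.  Categories
## are assigned against the nearest gene with a fixed precedence:
## promoter-proximal (within 2 kb of the TSS or overlapping the 5'UTR)
## > 3'UTR (overlapping the 3'UTR or within 2 kb of the TES) > exonic
## > intronic > intergenic.

#' Read gene models
#'
#' Accepts BED12 (exons from the block structure, UTRs from the thick/CDS
#' region) or a simple TSV with columns `gene_id`, `chrom`, `strand`,
#' `tss`, `tes` (1-based positions) and optional `body_start`, `body_end`.
#' For TSV input without exon structure, the whole gene body is treated as
#' one exon.
#'
#' @param path Input path; format chosen by the number of tab-separated
#'   columns and the presence of a header.
#' @return A list of class `gene_models`: `genes` (data.frame with
#'   `gene_id`, `chrom`, `strand`, `tss`, `tes`, `body_start`,
#'   `body_end`), `exons`, `utr5`, `utr3` (`GRanges` with `gene_id`).
#' @export
read_gene_models <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("gene_id", first)) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "strand", "tss", "tes")
    if (!all(need %in% names(df))) {
      stop("gene TSV needs columns: ", paste(need, collapse = ", "))
    }
    if (is.null(df$body_start)) df$body_start <- pmin(df$tss, df$tes)
    if (is.null(df$body_end)) df$body_end <- pmax(df$tss, df$tes)
    genes <- df[c("gene_id", "chrom", "strand", "tss", "tes",
                  "body_start", "body_end")]
    exons <- GenomicRanges::GRanges(genes$chrom,
                                    IRanges::IRanges(genes$body_start,
                                                     genes$body_end))
    exons$gene_id <- genes$gene_id
    empty <- GenomicRanges::GRanges()
    empty$gene_id <- character(0)
    return(structure(list(genes = genes, exons = exons,
                          utr5 = empty, utr3 = empty),
                     class = "gene_models"))
  }
  ## BED12
  bed <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(bed) < 12L) stop("expected BED12 or a gene TSV with header")
  chrom <- bed[[1L]]
  start1 <- bed[[2L]] + 1L
  end1 <- bed[[3L]]
  gene_id <- bed[[4L]]
  strand <- bed[[6L]]
  thick_s <- bed[[7L]] + 1L
  thick_e <- bed[[8L]]
  sizes <- lapply(strsplit(bed[[11L]], ","), as.integer)
  offs <- lapply(strsplit(bed[[12L]], ","), as.integer)
  genes <- data.frame(gene_id = gene_id, chrom = chrom, strand = strand,
                      tss = ifelse(strand == "-", end1, start1),
                      tes = ifelse(strand == "-", start1, end1),
                      body_start = start1, body_end = end1,
                      stringsAsFactors = FALSE)
  ex_list <- lapply(seq_len(nrow(bed)), function(i) {
    s <- start1[i] + offs[[i]]
    data.frame(chrom = chrom[i], start = s, end = s + sizes[[i]] - 1L,
               gene_id = gene_id[i], stringsAsFactors = FALSE)
  })
  ex <- do.call(rbind, ex_list)
  exons <- GenomicRanges::GRanges(ex$chrom, IRanges::IRanges(ex$start, ex$end))
  exons$gene_id <- ex$gene_id
  clip <- function(lo, hi, i) {
    s <- pmax(ex$start[ex$gene_id == gene_id[i]], lo)
    e <- pmin(ex$end[ex$gene_id == gene_id[i]], hi)
    keep <- s <= e
    if (!any(keep)) return(NULL)
    data.frame(chrom = chrom[i], start = s[keep], end = e[keep],
               gene_id = gene_id[i], stringsAsFactors = FALSE)
  }
  utr_rows <- function(before_thick) {
    rows <- lapply(seq_len(nrow(bed)), function(i) {
      if (thick_s[i] > thick_e[i]) return(NULL)  # non-coding: no UTRs
      upstream <- clip(start1[i], thick_s[i] - 1L, i)
      downstream <- clip(thick_e[i] + 1L, end1[i], i)
      five_is_upstream <- strand[i] != "-"
      if (before_thick == five_is_upstream) upstream else downstream
    })
    do.call(rbind, rows)
  }
  mk <- function(rows) {
    if (is.null(rows) || nrow(rows) == 0L) {
      g <- GenomicRanges::GRanges(); g$gene_id <- character(0); return(g)
    }
    g <- GenomicRanges::GRanges(rows$chrom,
                                IRanges::IRanges(rows$start, rows$end))
    g$gene_id <- rows$gene_id
    g
  }
  structure(list(genes = genes, exons = exons,
                 utr5 = mk(utr_rows(TRUE)), utr3 = mk(utr_rows(FALSE))),
            class = "gene_models")
}

#' Annotate peaks with nearest gene and genomic category
#'
#' The nearest gene is chosen by the distance from the peak midpoint to the
#' gene body (0 when the midpoint falls inside the body; ties go to the
#' lexicographically first `gene_id`).  The category follows the
#' precedence promoter-proximal > 3'UTR > exonic > intronic > intergenic,
#' evaluated against the assigned gene by any-overlap of the peak with the
#' relevant feature (TSS +/- `margin` window, UTRs, exons, gene body).
#' A peak is `proximal` when its distance to the gene body is at most
#' `margin` bp.
#'
#' @param peaks A `GRanges`.
#' @param genes A `gene_models` object.
#' @param margin Promoter/TES window and proximality margin in bp
#'   (default 2000).
#' @return A data.frame with columns `peak`, `gene_id`, `category`,
#'   `distance`, `proximal`.
#' @export
annotate_peaks <- function(peaks, genes, margin = 2000L) {
  stopifnot(is(peaks, "GRanges"), inherits(genes, "gene_models"))
  g <- genes$genes
  if (nrow(g) == 0L) stop("no gene models")
  g <- g[order(g$gene_id), ]
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  ps <- GenomicRanges::start(peaks)
  pe <- GenomicRanges::end(peaks)
  mid <- (ps + pe) %/% 2L
  n <- length(peaks)
  gene_id <- character(n)
  distance <- rep(Inf, n)
  category <- character(n)
  proximal <- logical(n)
  ex_by_gene <- split(seq_along(genes$exons), genes$exons$gene_id)
  u5_by_gene <- split(seq_along(genes$utr5), genes$utr5$gene_id)
  u3_by_gene <- split(seq_along(genes$utr3), genes$utr3$gene_id)
  overlaps_feature <- function(set, idx, s, e) {
    if (is.null(idx) || length(idx) == 0L) return(FALSE)
    fs <- GenomicRanges::start(set)[idx]
    fe <- GenomicRanges::end(set)[idx]
    any(s <= fe & e >= fs)
  }
  for (i in seq_len(n)) {
    gi <- which(g$chrom == chrom[i])
    if (length(gi) == 0L) {
      gene_id[i] <- NA_character_
      category[i] <- "intergenic"
      distance[i] <- Inf
      next
    }
    d_mid <- pmax(g$body_start[gi] - mid[i], mid[i] - g$body_end[gi], 0L)
    j <- gi[which.min(d_mid)]     # g sorted by gene_id => first on ties
    gene_id[i] <- g$gene_id[j]
    distance[i] <- max(g$body_start[j] - pe[i], ps[i] - g$body_end[j], 0L)
    proximal[i] <- distance[i] <= margin
    gid <- g$gene_id[j]
    tss_hit <- ps[i] <= g$tss[j] + margin & pe[i] >= g$tss[j] - margin
    tes_hit <- ps[i] <= g$tes[j] + margin & pe[i] >= g$tes[j] - margin
    body_hit <- ps[i] <= g$body_end[j] & pe[i] >= g$body_start[j]
    category[i] <-
      if (tss_hit || overlaps_feature(genes$utr5, u5_by_gene[[gid]], ps[i], pe[i])) {
        "promoter_proximal"
      } else if (tes_hit || overlaps_feature(genes$utr3, u3_by_gene[[gid]], ps[i], pe[i])) {
        "utr3"
      } else if (overlaps_feature(genes$exons, ex_by_gene[[gid]], ps[i], pe[i])) {
        "exonic"
      } else if (body_hit) {
        "intronic"
      } else {
        "intergenic"
      }
  }
  data.frame(peak = peak_names(peaks), gene_id = gene_id,
             category = category, distance = distance, proximal = proximal,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Rank genes by their most negative stage coefficient
#'
#' Each gene receives the minimum stage coefficient (alpha1) over its
#' proximal peaks (peaks within the proximality margin of the gene body);
#' genes with no proximal peak are omitted.  The result is sorted with the
#' most negative coefficient first, suitable as a ranked list for gene-set
#' enrichment tools.
#'
#' @param fits A `stage_fit` table.
#' @param annotations Output of [annotate_peaks()] on the same peaks.
#' @return A data.frame with columns `gene_id`, `coefficient`.
#' @export
rank_genes_by_coefficient <- function(fits, annotations) {
  stopifnot(inherits(fits, "stage_fit"))
  m <- match(annotations$peak, fits$peak)
  if (anyNA(m)) stop("annotated peak missing from the fit table")
  keep <- annotations$proximal & !is.na(annotations$gene_id)
  if (!any(keep)) {
    return(data.frame(gene_id = character(0), coefficient = numeric(0)))
  }
  a1 <- fits$alpha1[m[keep]]
  gid <- annotations$gene_id[keep]
  score <- tapply(a1, gid, min)
  out <- data.frame(gene_id = names(score), coefficient = as.numeric(score),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$coefficient, out$gene_id), , drop = FALSE]
}

#' Read a GWAS SNP table
#'
#' TSV with columns `chrom`, `pos` (1-based) and `pvalue` (association P in
#' (0, 1\]).
#'
#' @param path Input path.
#' @return A data.frame with `chrom`, `pos`, `pvalue`.
#' @export
read_snps <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "pvalue")
  if (!all(need %in% names(df))) {
    stop("SNP TSV needs columns: ", paste(need, collapse = ", "))
  }
  if (any(df$pvalue <= 0 | df$pvalue > 1)) stop("SNP p-values must be in (0, 1]")
  df[need]
}

#' GWAS SNP overlap with region sets
#'
#' Optionally extends each region by `extension` bp on both sides, assigns
#' each region the minimum GWAS P over the SNPs it contains (1 when it
#' contains none), and reports the proportion of regions whose minimum P
#' falls below `p_threshold`.
#'
#' @param regions A sorted `GRanges` (DARs, non-DARs or non-peaks).
#' @param snps SNP data.frame from [read_snps()].
#' @param extension Symmetric extension in bp (default 0; >= 0).
#' @param p_threshold Significance threshold on the per-region minimum P
#'   (default 5e-8).
#' @return A list: `min_p` (per-region vector), `proportion`, `n_regions`.
#' @export
snp_overlap <- function(regions, snps, extension = 0L, p_threshold = 5e-8) {
  stopifnot(is(regions, "GRanges"))
  if (extension < 0) stop("'extension' must be >= 0")
  if (length(regions) == 0L) {
    return(list(min_p = numeric(0), proportion = NA_real_, n_regions = 0L))
  }
  ext <- regions
  GenomicRanges::start(ext) <- pmax(GenomicRanges::start(ext) - extension, 1L)
  GenomicRanges::end(ext) <- GenomicRanges::end(ext) + extension
  snp_gr <- GenomicRanges::GRanges(snps$chrom,
                                   IRanges::IRanges(snps$pos, snps$pos))
  hits <- GenomicRanges::findOverlaps(ext, snp_gr, ignore.strand = TRUE)
  min_p <- rep(1, length(regions))
  if (length(hits)) {
    agg <- tapply(snps$pvalue[S4Vectors::subjectHits(hits)],
                  S4Vectors::queryHits(hits), min)
    min_p[as.integer(names(agg))] <- as.numeric(agg)
  }
  list(min_p = min_p,
       proportion = mean(min_p < p_threshold),
       n_regions = length(regions))
}

#' Construct non-peak control regions
#'
#' For each peak, emits the immediately adjacent interval of the same
#' width on the chosen side.  A flank that would overlap any peak (or fall
#' before the chromosome start) is skipped.
#'
#' @param peaks A sorted `GRanges`.
#' @param side `"downstream"` (default) or `"upstream"`.
#' @return A `GRanges` of non-peak regions.
#' @export
make_nonpeaks <- function(peaks, side = c("downstream", "upstream")) {
  stopifnot(is(peaks, "GRanges"))
  side <- match.arg(side)
  w <- GenomicRanges::width(peaks)
  if (side == "downstream") {
    fs <- GenomicRanges::end(peaks) + 1L
    fe <- GenomicRanges::end(peaks) + w
  } else {
    fs <- GenomicRanges::start(peaks) - w
    fe <- GenomicRanges::start(peaks) - 1L
  }
  ok <- fs >= 1L
  fl <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks)[ok],
                               IRanges::IRanges(fs[ok], fe[ok]))
  clash <- IRanges::overlapsAny(fl, peaks, ignore.strand = TRUE)
  n_skip <- sum(clash) + sum(!ok)
  if (n_skip > 0L) {
    message("make_nonpeaks: skipped ", n_skip, " flank(s) colliding with peaks")
  }
  sort_intervals(fl[!clash])
}
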