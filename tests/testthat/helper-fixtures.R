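## Shared fixtures and independent oracles for the test suite.

gr <- function(chrom, start1, end1, ...) {
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start1, end1), ...)
}

## Build an acc_counts object from a bare matrix with minimal metadata.
make_counts <- function(counts, stage = NULL, library_size = NULL) {
  n <- ncol(counts)
  if (is.null(stage)) stage <- rep_len(0:2, n)
  if (is.null(library_size)) library_size <- rep(3e7, n)
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)), tissue = "retina",
    region_code = rep_len(c(1, -1), n), stage_code = stage,
    gender_code = rep_len(c(1, -1), n), age = 85, interval = 8,
    library_size = library_size, stringsAsFactors = FALSE)
  colnames(counts) <- samples$sample_id
  peaks <- gr("chrS", seq(1, by = 5000, length.out = nrow(counts)),
              seq(1, by = 5000, length.out = nrow(counts)) + 499)
  acc_counts(counts, peaks, samples)
}

write_bed_lines <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  f
}

## Independent brute-force Benjamini-Hochberg (step-up with cummin).
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m / (m:1) * p[o]))[ro]
}

## Brute-force fragment counting: O(F x P) double loop on 1-based closed
## coordinates.
count_oracle <- function(frags, peaks) {
  out <- integer(length(peaks))
  for (i in seq_along(peaks)) {
    for (j in seq_along(frags)) {
      same <- as.character(GenomicRanges::seqnames(peaks)[i]) ==
        as.character(GenomicRanges::seqnames(frags)[j])
      if (same &&
          GenomicRanges::start(frags)[j] <= GenomicRanges::end(peaks)[i] &&
          GenomicRanges::end(frags)[j] >= GenomicRanges::start(peaks)[i]) {
        out[i] <- out[i] + 1L
      }
    }
  }
  out
}

## Brute-force FOS from first principles: recount insertions in explicitly
## enumerated central / flank intervals, then apply the defining formula.
fos_oracle <- function(ins, chrom, s, e) {
  L <- e - s + 1
  cnt <- function(lo, hi) sum(ins$chrom == chrom & ins$pos >= lo & ins$pos <= hi)
  n_c <- cnt(s, e)
  n_l <- cnt(s - 3 * L, s - 1) / 3
  n_r <- cnt(e + 1, e + 3 * L) / 3
  min(-log2((n_c + 1) / (n_l + 1)), -log2((n_c + 1) / (n_r + 1)))
}

## Upper-tail hypergeometric by explicit combinatorial enumeration.
hyper_oracle <- function(k, n, N, K) {
  if (K == 0) return(1)
  j <- k:min(K, n)
  sum(choose(n, j) * choose(N - n, K - j)) / choose(N, K)
}
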