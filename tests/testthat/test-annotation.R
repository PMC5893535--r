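## A small two-gene model used across the annotation tests:
## geneA: + strand, body 1-based [10001, 20000], TSS 10001, TES 20000,
##        exons [10001,10500] (5'UTR part [10001,10200]), [15000,15400]
##        and [19000,20000] (3'UTR part [19501,20000])
## geneB: - strand, body [50001, 56000], TSS 56000, TES 50001, single exon
fixture_genes <- function() {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstrand\ttss\ttes",
               "geneB\tchr1\t-\t56000\t50001"), tsv)
  tsvm <- read_gene_models(tsv)
  bed <- tempfile(fileext = ".bed")
  writeLines(paste(c("chr1", 10000, 20000, "geneA", 0, "+",
                     10200, 19500, 0, 3, "500,401,1001", "0,4999,8999"),
                   collapse = "\t"), bed)
  bedm <- read_gene_models(bed)
  genes <- structure(list(
    genes = rbind(bedm$genes, tsvm$genes),
    exons = c(bedm$exons, tsvm$exons),
    utr5 = bedm$utr5, utr3 = bedm$utr3), class = "gene_models")
  genes
}

test_that("gene model readers recover TSS/TES, exons and UTRs", {
  g <- fixture_genes()
  a <- g$genes[g$genes$gene_id == "geneA", ]
  expect_equal(a$tss, 10001)
  expect_equal(a$tes, 20000)
  expect_equal(GenomicRanges::start(g$utr5), 10001)
  expect_equal(GenomicRanges::end(g$utr5), 10200)
  expect_equal(GenomicRanges::start(g$utr3), 19501)
  b <- g$genes[g$genes$gene_id == "geneB", ]
  expect_equal(b$body_start, 50001)   # minus strand: TSS at the body end
  expect_equal(b$tss, 56000)
})

test_that("annotate_peaks applies the category precedence", {
  g <- fixture_genes()
  peaks <- c(gr("chr1", 9300, 9600),     # 500 bp upstream of geneA TSS
             gr("chr1", 13000, 13300),   # intron, > 2 kb from TSS/TES
             gr("chr1", 15100, 15200),   # internal exon (not UTR)
             gr("chr1", 19600, 19700),   # 3'UTR
             gr("chr1", 80001, 80100),   # far from both genes
             gr("chr1", 53000, 53100))   # inside geneB body (exon fallback)
  ann <- annotate_peaks(peaks, g)
  expect_equal(ann$category,
               c("promoter_proximal", "intronic", "exonic", "utr3",
                 "intergenic", "exonic"))
  expect_equal(ann$gene_id, c("geneA", "geneA", "geneA", "geneA",
                              "geneB", "geneB"))
  expect_equal(ann$distance[1], 10001 - 9600)
  expect_equal(ann$distance[2], 0)
  expect_true(ann$proximal[1])
  expect_false(ann$proximal[5])
  # every peak gets exactly one category
  expect_equal(nrow(ann), length(peaks))
})

test_that("equidistant peaks go to the lexicographically first gene", {
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstrand\ttss\ttes",
               "geneZ\tchr1\t+\t1000\t2000",
               "geneA\tchr1\t+\t8000\t9000"),
             tsv)
  g <- read_gene_models(tsv)
  mid <- gr("chr1", 4950, 5050)   # midpoint 5000, 3000 bp from both bodies
  ann <- annotate_peaks(mid, g)
  expect_equal(ann$gene_id, "geneA")
})

test_that("rank_genes_by_coefficient takes the minimum over proximal peaks", {
  tmpl <- balanced_sample_templates(3)
  sim <- simulate_cohort(cohort_config(n_peaks = 4, samples = tmpl, seed = 22))
  fit <- fit_stage_model(normalize_counts(sim$counts))
  fit$alpha1 <- c(-0.3, -0.9, -0.2, 0.5)
  ann <- data.frame(peak = fit$peak,
                    gene_id = c("g1", "g1", "g2", "g3"),
                    category = "intergenic",
                    distance = c(0, 100, 0, 3000),
                    proximal = c(TRUE, TRUE, TRUE, FALSE))
  ranked <- rank_genes_by_coefficient(fit, ann)
  # g3 has no proximal peak and is omitted; g1 takes min(-0.3, -0.9)
  expect_equal(ranked$gene_id, c("g1", "g2"))
  expect_equal(ranked$coefficient, c(-0.9, -0.2))
  # score never exceeds the per-gene minimum
  expect_lte(ranked$coefficient[1], min(fit$alpha1[1:2]))
})

test_that("snp_overlap takes per-region minimum P with a default of 1", {
  regions <- gr("chr1", c(1001, 5001, 9001), c(2000, 6000, 10000))
  snps <- data.frame(chrom = "chr1", pos = c(1500, 1600, 5500),
                     pvalue = c(0.3, 1e-8, 0.7))
  ov <- snp_overlap(regions, snps, p_threshold = 5e-8)
  expect_equal(ov$min_p, c(1e-8, 0.7, 1))
  expect_equal(ov$proportion, 1 / 3)
  # no SNP anywhere: all 1, proportion 0
  none <- snp_overlap(regions, snps[0, ], p_threshold = 5e-8)
  expect_equal(none$min_p, rep(1, 3))
  expect_equal(none$proportion, 0)
  # extension pulls in a previously outside SNP
  near <- data.frame(chrom = "chr1", pos = 2400, pvalue = 1e-9)
  expect_equal(snp_overlap(regions, near)$proportion, 0)
  expect_equal(snp_overlap(regions, near, extension = 500)$proportion, 1 / 3)
  expect_error(snp_overlap(regions, snps, extension = -1), "extension")
})

test_that("snp_overlap proportion is monotone in extension and threshold", {
  set.seed(23)
  starts <- sort(sample.int(1e6, 50))
  regions <- merge_proximal(gr("chr1", starts, starts + 500), 10)
  snps <- data.frame(chrom = "chr1", pos = sample.int(1e6, 200),
                     pvalue = 10^runif(200, -10, 0))
  props_ext <- vapply(c(0, 1000, 5000, 20000), function(e) {
    snp_overlap(regions, snps, extension = e, p_threshold = 1e-4)$proportion
  }, numeric(1))
  expect_true(all(diff(props_ext) >= 0))
  props_thr <- vapply(c(1e-8, 1e-4, 1e-2, 1), function(t) {
    snp_overlap(regions, snps, p_threshold = t)$proportion
  }, numeric(1))
  expect_true(all(diff(props_thr) >= 0))
})

test_that("make_nonpeaks emits same-width flanks and skips collisions", {
  p <- gr("chr1", c(1001, 1501), c(1200, 1800))
  np <- suppressMessages(make_nonpeaks(p))
  # flank of peak 1 ([1201,1400]) fits; flank of peak 2 is clear too
  expect_equal(GenomicRanges::width(np), c(200, 300))
  expect_equal(GenomicRanges::start(np), c(1201, 1801))
  # colliding flank is skipped
  tight <- gr("chr1", c(1001, 1250), c(1200, 1400))
  expect_message(np2 <- make_nonpeaks(tight), "skipped")
  expect_length(np2, 1L)
  # upstream side configurable; flanks at the chromosome start are dropped
  up <- suppressMessages(make_nonpeaks(gr("chr1", c(51, 5001), c(250, 5200)),
                                       side = "upstream"))
  expect_length(up, 1L)
  expect_equal(GenomicRanges::start(up), 4801)
  # width distribution preserved for isolated peaks
  set.seed(24)
  starts <- seq(1e5, by = 1e4, length.out = 30)
  w <- sample(200:800, 30, replace = TRUE)
  iso <- gr("chr1", starts, starts + w - 1)
  expect_equal(GenomicRanges::width(suppressMessages(make_nonpeaks(iso))), w)
})
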