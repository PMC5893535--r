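test_that("insertions derive from fragment ends with Tn5 offsets", {
  # BED fragment [100, 200): default offsets give 0-based positions 104, 195
  f <- gr("chr1", 101, 200)
  ins <- insertions_from_fragments(f)
  expect_equal(sort(ins$pos - 1L), c(104L, 195L))
  # offset applied to the exclusive end; -1 recovers the last covered base
  naive <- insertions_from_fragments(f, shift_plus = 0L, shift_minus = -1L)
  expect_equal(sort(naive$pos - 1L), c(100L, 199L))
  # empty input -> empty multiset
  expect_equal(nrow(insertions_from_fragments(GenomicRanges::GRanges())), 0L)
})

test_that("compute_fos reproduces the worked example and sign behavior", {
  # motif of length 10 at 1-based [1001, 1010]; flanks are 30 bp each
  site <- gr("chr1", 1001, 1010)
  ins <- data.frame(chrom = "chr1",
                    pos = c(rep(975, 21), rep(1025, 45)))
  res <- compute_fos(ins, site)
  expect_equal(res$N_C, 0)
  expect_equal(res$N_L, 7)
  expect_equal(res$N_R, 15)
  expect_equal(res$fos, 3)    # min(-log2(1/8), -log2(1/16))

  # perfectly uniform insertions: one per bp everywhere -> FOS exactly 0
  uni <- data.frame(chrom = "chr1", pos = 941:1070)
  expect_equal(compute_fos(uni, site)$fos, 0)

  # central excess -> negative FOS
  hot <- data.frame(chrom = "chr1", pos = rep(1005, 50))
  expect_lt(compute_fos(hot, site)$fos, 0)
})

test_that("compute_fos matches brute-force interval recounting", {
  set.seed(20)
  for (rep in 1:25) {
    L <- sample(5:20, 1)
    s <- sample(500:2000, 1)
    e <- s + L - 1
    n_ins <- sample(0:400, 1)
    ins <- data.frame(chrom = "chr1",
                      pos = sample((s - 4 * L):(e + 4 * L), n_ins, replace = TRUE))
    got <- compute_fos(ins, gr("chr1", s, e))
    expect_equal(got$fos, fos_oracle(ins, "chr1", s, e))
  }
})

test_that("insertion profiles aggregate and normalize around motif centers", {
  sites <- gr("chr1", c(1001, 5001), c(1010, 5010))
  # uniform insertions across window + flanks of both sites -> flat profile
  ins <- data.frame(chrom = "chr1", pos = c(700:1300, 4700:5300))
  pr <- profile_at_motifs(ins, sites)
  expect_length(pr$counts, 200L)
  expect_true(all(pr$counts == 2))
  expect_equal(pr$flank_total, 2 * 300)
  expect_true(pr$norm_valid)
  expect_equal(sum(pr$normalized), sum(pr$counts) / pr$flank_total)

  # single central spike
  spike <- data.frame(chrom = "chr1", pos = c(1005, 900))
  pr2 <- profile_at_motifs(spike, sites[1])
  expect_equal(sum(pr2$counts), 1)
  expect_equal(pr2$counts[pr2$positions == 0], 1)

  # zero flank insertions -> flagged null normalization
  pr3 <- profile_at_motifs(data.frame(chrom = "chr1", pos = 1005), sites[1])
  expect_false(pr3$norm_valid)
  expect_true(all(is.na(pr3$normalized)))
})

test_that("minus-strand sites are positionally flipped", {
  plus <- gr("chr1", 1001, 1010, strand = "+")
  minus <- gr("chr1", 1001, 1010, strand = "-")
  # asymmetric insertions left of the center
  ins <- data.frame(chrom = "chr1", pos = c(rep(960, 3), 1080))
  pp <- profile_at_motifs(ins, plus)
  pm <- profile_at_motifs(ins, minus)
  expect_equal(pp$counts, rev(pm$counts))
  # aggregate over a site and its mirrored opposite-strand twin is symmetric
  both <- profile_at_motifs(ins, c(plus, minus))
  expect_equal(both$counts, rev(both$counts))
  # site order does not change the aggregate
  expect_equal(profile_at_motifs(ins, c(minus, plus))$counts, both$counts)
})

test_that("footprint enrichment matches exhaustive hypergeometric enumeration", {
  set.seed(21)
  for (rep in 1:20) {
    N <- sample(10:50, 1)
    n <- sample(2:(N - 2), 1)
    starts <- seq(1, by = 1000, length.out = N)
    regions <- gr("chr1", starts, starts + 200)
    dars <- regions[seq_len(n)]
    nons <- regions[(n + 1):N]
    K <- sample(1:N, 1)
    hit <- sample(N, K)
    sites <- gr(rep("chr1", K), starts[hit] + 50, starts[hit] + 60,
                motif_id = rep("M1", K))
    res <- footprint_enrichment(sites, dars, nons)
    k <- sum(hit <= n)
    expect_equal(res$k, k)
    expect_equal(res$K, K)
    expect_equal(res$pvalue, hyper_oracle(k, n, N, K), tolerance = 1e-12)
    expect_gt(res$pvalue, 0)
    expect_lte(res$pvalue, 1)
  }
})

test_that("footprint enrichment closed forms and error cases", {
  starts <- seq(1, by = 1000, length.out = 50)
  regions <- gr("chr1", starts, starts + 200)
  dars <- regions[1:5]            # 10% of the universe
  nons <- regions[6:50]
  # all 5 sites in DARs: p = C(n,5)/C(N,5)
  sites <- gr("chr1", starts[1:5] + 10, starts[1:5] + 20,
              motif_id = rep("M1", 5))
  res <- footprint_enrichment(sites, dars, nons)
  expect_equal(res$pvalue, choose(5, 5) * choose(45, 0) / choose(50, 5))
  # no footprinted region -> p = 1
  far <- gr("chr2", 1, 10, motif_id = "M2")
  expect_equal(suppressWarnings(footprint_enrichment(far, dars, nons))$pvalue, 1)
  # overlapping DAR/non-DAR sets are rejected
  expect_error(footprint_enrichment(sites, dars, regions[5:50]), "disjoint")
})
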