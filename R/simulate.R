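## Synthetic cohorts with known ground truth.
##
## The generator mirrors the statistical structure of a postmortem
## retina/RPE ATAC-Seq cohort: per-peak baseline log2 signal, a planted
## (negative) disease-stage effect in a fraction of peaks, additive
## confounder effects (region, gender, age, procurement interval),
## per-sample library sizes, and negative binomial count noise with a
## common biological dispersion.  Expected counts follow
##   mu = S_L / 1e8 * 2^(a0 + a1*stage + a2*region + a3*gender
##                        + a4*age + a5*interval)
## so that the library-size normalization recovers the linear predictor
## (up to the +1 pseudo-count) and OLS recovery tests are meaningful.

#' Sample templates emulating a retina cohort
#'
#' 25 samples: 11 normal, 5 early-stage, 9 late-stage, with macular
#' (`region_code` +1) and male (`gender_code` +1) counts matching a
#' realistic postmortem cohort.  Ages and procurement intervals are drawn
#' later by [simulate_cohort()] from per-stage ranges.
#'
#' @return A data.frame with `sample_id`, `tissue`, `stage_code`,
#'   `region_code`, `gender_code`.
#' @export
retina_sample_templates <- function() {
  stage <- rep(0:2, c(11L, 5L, 9L))
  region <- unlist(list(rep(c(1, -1), c(5L, 6L)),
                        rep(c(1, -1), c(2L, 3L)),
                        rep(c(1, -1), c(5L, 4L))))
  gender <- unlist(list(rep(c(1, -1), c(5L, 6L)),
                        rep(c(1, -1), c(2L, 3L)),
                        rep(c(1, -1), c(2L, 7L))))
  data.frame(sample_id = sprintf("RET%02d", seq_along(stage)),
             tissue = "retina", stage_code = stage,
             region_code = region, gender_code = gender,
             stringsAsFactors = FALSE)
}

#' Balanced sample templates
#'
#' `n_per_stage` samples in each of the three stages, with region and
#' gender alternating within stage; convenient for recovery simulations.
#'
#' @param n_per_stage Samples per stage (default 8).
#' @return A template data.frame as in [retina_sample_templates()].
#' @export
balanced_sample_templates <- function(n_per_stage = 8L) {
  stage <- rep(0:2, each = n_per_stage)
  n <- length(stage)
  data.frame(sample_id = sprintf("SYN%02d", seq_len(n)),
             tissue = "retina", stage_code = stage,
             region_code = rep_len(c(1, -1), n),
             gender_code = rep_len(c(1, 1, -1, -1), n),
             stringsAsFactors = FALSE)
}

#' Cohort simulation configuration
#'
#' Defaults describe a realistic human bulk ATAC-Seq cohort: baseline
#' normalized signal around 7.5 (above the 6.5 retention threshold),
#' stage effects of about -0.4 log2 units per stage in 90% of peaks,
#' mild confounder effects (macular region and longer procurement
#' intervals lower the signal), library sizes of 20-50 million qualified
#' fragments, and a biological coefficient of variation of 0.4
#' (NB dispersion 0.16), typical for human cohorts.
#'
#' @param n_peaks Number of peaks.
#' @param samples Template data.frame (stage/region/gender per sample).
#' @param baseline_mean,baseline_sd Per-peak baseline (alpha0)
#'   distribution, log2 scale.
#' @param stage_effect_mean,stage_effect_sd Planted stage coefficient
#'   (alpha1) distribution for affected peaks; mean should be <= 0.
#' @param fraction_affected Fraction of peaks receiving a nonzero alpha1.
#' @param beta_region,beta_gender,beta_age,beta_interval Confounder
#'   coefficients (alpha2..alpha5), shared by all peaks.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2).
#' @param libsize_range Range for per-sample library sizes.
#' @param age_ranges,interval_ranges Per-stage lists of c(lo, hi) ranges
#'   from which ages (years) and procurement intervals (hours) are drawn.
#' @param noise `"nb"` (negative binomial) or `"lnp"`
#'   (lognormal-Poisson with matched variance), for robustness checks.
#' @param seed Integer seed; every draw in [simulate_cohort()] flows from
#'   it.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_peaks = 1000L,
                          samples = retina_sample_templates(),
                          baseline_mean = 7.5, baseline_sd = 1.2,
                          stage_effect_mean = -0.4, stage_effect_sd = 0.1,
                          fraction_affected = 0.9,
                          beta_region = -0.1, beta_gender = 0.02,
                          beta_age = -0.005, beta_interval = -0.02,
                          dispersion = 0.16,
                          libsize_range = c(2e7, 5e7),
                          age_ranges = list(c(79, 92), c(82, 87), c(90, 94)),
                          interval_ranges = list(c(7, 13), c(3.5, 7), c(4.5, 9)),
                          noise = c("nb", "lnp"),
                          seed = 1L) {
  noise <- match.arg(noise)
  if (n_peaks < 1L) stop("'n_peaks' must be >= 1")
  if (fraction_affected < 0 || fraction_affected > 1) {
    stop("'fraction_affected' must be in [0, 1]")
  }
  if (dispersion <= 0) stop("'dispersion' must be > 0")
  structure(as.list(environment()), class = "cohort_config")
}

#' Simulate a cohort with planted effects
#'
#' Draws per-sample covariates and library sizes, per-peak coefficients,
#' and a raw count matrix under the configured noise model.  Fully
#' reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A list: `counts` (an `acc_counts`), `truth` (list with per-peak
#'   `alpha0`, `alpha1`, the confounder betas, `affected` flags and
#'   per-sample `library_size`), `config`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  tmpl <- config$samples
  n_s <- nrow(tmpl)
  stage_idx <- tmpl$stage_code + 1L
  age <- vapply(stage_idx, function(k) {
    r <- config$age_ranges[[k]]; stats::runif(1, r[1], r[2])
  }, numeric(1))
  interval <- vapply(stage_idx, function(k) {
    r <- config$interval_ranges[[k]]; stats::runif(1, r[1], r[2])
  }, numeric(1))
  libsize <- round(stats::runif(n_s, config$libsize_range[1],
                                config$libsize_range[2]))
  samples <- data.frame(tmpl, age = round(age, 1),
                        interval = round(interval, 1),
                        library_size = libsize,
                        stringsAsFactors = FALSE)

  n_p <- config$n_peaks
  alpha0 <- stats::rnorm(n_p, config$baseline_mean, config$baseline_sd)
  affected <- stats::runif(n_p) < config$fraction_affected
  alpha1 <- ifelse(affected,
                   stats::rnorm(n_p, config$stage_effect_mean,
                                config$stage_effect_sd), 0)
  eta <- outer(alpha0, rep(1, n_s)) +
    outer(alpha1, samples$stage_code) +
    config$beta_region * matrix(samples$region_code, n_p, n_s, byrow = TRUE) +
    config$beta_gender * matrix(samples$gender_code, n_p, n_s, byrow = TRUE) +
    config$beta_age * matrix(samples$age, n_p, n_s, byrow = TRUE) +
    config$beta_interval * matrix(samples$interval, n_p, n_s, byrow = TRUE)
  mu <- sweep(2^eta, 2L, libsize / 1e8, "*")
  counts <- matrix(0L, n_p, n_s)
  if (config$noise == "nb") {
    counts[] <- stats::rnbinom(n_p * n_s, mu = mu, size = 1 / config$dispersion)
  } else {
    sdlog <- sqrt(log1p(config$dispersion))
    lambda <- mu * stats::rlnorm(n_p * n_s, -sdlog^2 / 2, sdlog)
    counts[] <- stats::rpois(n_p * n_s, lambda)
  }
  colnames(counts) <- samples$sample_id
  peaks <- synthetic_peaks(n_p)
  cm <- acc_counts(counts, peaks, samples)
  truth <- list(alpha0 = alpha0, alpha1 = alpha1, affected = affected,
                beta_region = config$beta_region,
                beta_gender = config$beta_gender,
                beta_age = config$beta_age,
                beta_interval = config$beta_interval,
                library_size = libsize)
  list(counts = cm, truth = truth, config = config)
}

## Deterministic synthetic peak coordinates: 500-bp peaks every 5 kb on a
## synthetic chromosome.
synthetic_peaks <- function(n_peaks, width = 500L, spacing = 5000L,
                            chrom = "chrS") {
  start1 <- 1L + spacing * (seq_len(n_peaks) - 1L)
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start1, start1 + width - 1L))
  gr$name <- peak_names(gr)
  gr
}

#' Simulate a fragment BED file over peaks
#'
#' Places fragments overlapping each peak (Poisson count at the peak's
#' rate, uniform placement) plus uniform background fragments between
#' peaks.  Fragment lengths follow a two-component mixture of
#' sub-nucleosomal (60-120 bp) and mono-nucleosomal (180-250 bp) sizes.
#' Output is a sorted BED3, byte-identical for a given seed.
#'
#' @param peaks A `GRanges`.
#' @param rates Expected fragment count per peak (length 1 or
#'   `length(peaks)`).
#' @param background Expected background fragments per bp outside peaks
#'   (default 0).
#' @param sub_frac Mixture weight of the sub-nucleosomal component
#'   (default 0.6).
#' @param path Output path (default a tempfile).
#' @param seed Integer seed.
#' @return The path, with attribute `"n_fragments"`.
#' @export
simulate_fragments <- function(peaks, rates, background = 0,
                               sub_frac = 0.6, path = tempfile(fileext = ".bed"),
                               seed = 1L) {
  stopifnot(is(peaks, "GRanges"))
  if (any(rates < 0) || background < 0) stop("rates must be >= 0")
  set.seed(seed)
  rates <- rep_len(rates, length(peaks))
  frag_len <- function(n) {
    sub <- stats::runif(n) < sub_frac
    ifelse(sub,
           sample(60:120, n, replace = TRUE),
           sample(180:250, n, replace = TRUE))
  }
  rows <- list()
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  ps <- GenomicRanges::start(peaks) - 1L   # 0-based
  pe <- GenomicRanges::end(peaks)
  for (i in seq_along(peaks)) {
    k <- stats::rpois(1L, rates[i])
    if (k == 0L) next
    len <- frag_len(k)
    lo <- pmax(ps[i] - len + 1L, 0L)
    start0 <- floor(stats::runif(k, lo, pe[i]))  # overlaps peak by >= 1 bp
    rows[[length(rows) + 1L]] <-
      data.frame(chrom = chrom[i], start = as.integer(start0),
                 end = as.integer(start0 + len), stringsAsFactors = FALSE)
  }
  if (background > 0) {
    for (ch in unique(chrom)) {
      span <- max(pe[chrom == ch]) + 10000L
      k <- stats::rpois(1L, background * span)
      if (k == 0L) next
      len <- frag_len(k)
      start0 <- floor(stats::runif(k, 0, span))
      rows[[length(rows) + 1L]] <-
        data.frame(chrom = ch, start = as.integer(start0),
                   end = as.integer(start0 + len), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    file.create(path)
    attr(path, "n_fragments") <- 0L
    return(path)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  attr(path, "n_fragments") <- nrow(df)
  path
}

#' Simulate Tn5 insertions around a motif with a planted footprint
#'
#' Insertions are Poisson per bp at `flank_rate` in the two 3L flanks and
#' at `mean(flank_rate) * (1 - occupancy)` in the central motif span, so
#' `occupancy` = 0 gives a flat profile and `occupancy` = 1 a fully
#' protected center.  The closed-form expectation of the footprint
#' occupancy score under these rates is returned for comparison with
#' [compute_fos()].
#'
#' @param site A length-1 `GRanges` motif occurrence.
#' @param flank_rate Expected insertions per bp in the flanks (length 1,
#'   or 2 for asymmetric left/right rates).
#' @param occupancy Footprint depth in \[0, 1\].
#' @param seed Integer seed.
#' @return A list: `insertions` (data.frame `chrom`, `pos`),
#'   `expected_fos`, `rates` (center/left/right per-bp rates).
#' @export
simulate_footprint_insertions <- function(site, flank_rate, occupancy,
                                          seed = 1L) {
  stopifnot(is(site, "GRanges"), length(site) == 1L)
  if (occupancy < 0 || occupancy > 1) stop("'occupancy' must be in [0, 1]")
  set.seed(seed)
  L <- GenomicRanges::width(site)
  fr <- rep_len(flank_rate, 2L)
  rate_c <- mean(fr) * (1 - occupancy)
  s <- GenomicRanges::start(site)
  e <- GenomicRanges::end(site)
  chrom <- as.character(GenomicRanges::seqnames(site))
  draw <- function(lo, hi, rate) {
    pos <- lo:hi
    k <- stats::rpois(length(pos), rate)
    rep(pos, k)
  }
  pos <- c(draw(s - 3L * L, s - 1L, fr[1L]),
           draw(s, e, rate_c),
           draw(e + 1L, e + 3L * L, fr[2L]))
  expected_fos <- min(-log2((rate_c * L + 1) / (fr[1L] * L + 1)),
                      -log2((rate_c * L + 1) / (fr[2L] * L + 1)))
  list(insertions = data.frame(chrom = rep(chrom, length(pos)),
                               pos = as.integer(pos),
                               stringsAsFactors = FALSE),
       expected_fos = expected_fos,
       rates = c(center = rate_c, left = fr[1L], right = fr[2L]))
}
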