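#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment with monotonicity enforcement, via
#' [stats::p.adjust()] after validating the input range.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values (FDR) in \[0, 1\].
#' @export
bh_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues < 0) || any(pvalues > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

## Conditional negative binomial exact test for two group sums.
## The sum of n iid NB(mu, size = 1/phi) counts is NB(n*mu, size = n/phi).
## Given equal per-sample means under H0, the distribution of the group-B
## sum conditional on the total is free of the mean, so p(b | T) is computed
## by normalizing dnbinom products over the support.  The two-sided p-value
## sums the probabilities of all outcomes no more likely than the observed
## one (the usual exact-test rule).  For large totals the support is
## truncated to a +/- ~1e-12 mass window; excluded mass is added to the
## p-value, which can only make it (negligibly) conservative.
nb_exact_pvalue <- function(a_sum, b_sum, n_a, n_b, phi) {
  total <- a_sum + b_sum
  if (total == 0) return(1)
  lambda <- total / (n_a + n_b)
  size_a <- n_a / phi
  size_b <- n_b / phi
  lo <- 0
  hi <- total
  if (total > 20000) {
    qb <- stats::qnbinom(c(1e-13, 1 - 1e-13), size = size_b, mu = n_b * lambda)
    qa <- stats::qnbinom(c(1e-13, 1 - 1e-13), size = size_a, mu = n_a * lambda)
    lo <- max(0, min(qb[1], total - qa[2]))
    hi <- min(total, max(qb[2], total - qa[1]))
    lo <- min(lo, b_sum)
    hi <- max(hi, b_sum)
  }
  b <- lo:hi
  logp <- stats::dnbinom(b, size = size_b, mu = n_b * lambda, log = TRUE) +
    stats::dnbinom(total - b, size = size_a, mu = n_a * lambda, log = TRUE)
  logp <- logp - max(logp)
  p <- exp(logp)
  norm <- sum(p)
  obs <- p[b_sum - lo + 1L]
  pv <- sum(p[p <= obs * (1 + 1e-10)]) / norm
  if (lo > 0 || hi < total) pv <- pv + 1e-12  # truncated-mass allowance
  min(pv, 1)
}

## Method-of-moments common dispersion on library-size-scaled counts.
## Within each group, phi solves var = mu + phi * mu^2 per peak; the
## denominator uses the unbiased estimate of mu^2 (m^2 - v/n, since
## E[m^2] = mu^2 + var(m)).  Per-peak estimates are averaged with equal
## weight across peaks, which is markedly more stable than a
## mu^2-weighted ratio of sums when baseline intensities span decades.
estimate_common_dispersion <- function(scaled, groups) {
  num <- 0
  den <- 0
  for (g in groups) {
    y <- scaled[, g, drop = FALSE]
    n <- length(g)
    if (n < 2L) next
    m <- rowMeans(y)
    v <- apply(y, 1L, stats::var)
    num <- num + (v - m) * (n - 1)
    den <- den + (m^2 - v / n) * (n - 1)
  }
  if (all(den <= 0)) return(1e-8)
  max(mean(pmax(num / pmax(den, 1), 0)), 1e-8)
}

#' Pairwise differential accessibility test
#'
#' Tests each peak for a difference in accessibility between two sample
#' groups using a negative binomial exact test on library-size-scaled group
#' sums, with a single common dispersion estimated from the data by the
#' method of moments.  The log2 fold change is computed from scaled group
#' means with a pseudo-count of 0.5 per group mean.  A peak is flagged
#' significant when `|log2fc| > fc_threshold` and BH FDR `< fdr_threshold`.
#'
#' @param x An `acc_counts` object.
#' @param group_a,group_b Disjoint, non-empty character vectors of sample
#'   ids (fold changes are B vs A).
#' @param fc_threshold Absolute log2 fold-change cut (default 0.8).
#' @param fdr_threshold FDR cut (default 0.05).
#' @param dispersion Optional fixed NB dispersion; estimated when `NULL`.
#' @return A data.frame of class `acc_diff` with columns `peak`,
#'   `mean_signal` (mean C_N over the compared samples), `log2fc`,
#'   `pvalue`, `fdr`, `significant`, `direction` (`reduced`/`increased`/
#'   `tie`), and the dispersion used as attribute `"dispersion"`.
#' @export
differential_test <- function(x, group_a, group_b, fc_threshold = 0.8,
                              fdr_threshold = 0.05, dispersion = NULL) {
  stopifnot(inherits(x, "acc_counts"))
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  if (length(intersect(group_a, group_b)) > 0L) {
    stop("groups must be disjoint")
  }
  ids <- x$samples$sample_id
  if (!all(c(group_a, group_b) %in% ids)) stop("unknown sample id in groups")

  sl <- x$samples$library_size[match(c(group_a, group_b), ids)]
  sel <- x$counts[, c(group_a, group_b), drop = FALSE]
  s0 <- exp(mean(log(sl)))
  scaled <- sweep(sel, 2L, s0 / sl, "*")
  ia <- seq_along(group_a)
  ib <- length(group_a) + seq_along(group_b)

  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(scaled, list(ia, ib))
  }

  mean_a <- rowMeans(scaled[, ia, drop = FALSE])
  mean_b <- rowMeans(scaled[, ib, drop = FALSE])
  log2fc <- log2((mean_b + 0.5) / (mean_a + 0.5))

  a_sum <- round(rowSums(scaled[, ia, drop = FALSE]))
  b_sum <- round(rowSums(scaled[, ib, drop = FALSE]))
  pvalue <- vapply(seq_len(nrow(scaled)), function(i) {
    nb_exact_pvalue(a_sum[i], b_sum[i], length(ia), length(ib), dispersion)
  }, numeric(1))

  norm_vals <- log2(sweep(sel, 2L, sl, "/") * 1e8 + 1)
  mean_signal <- rowMeans(norm_vals)

  fdr <- bh_adjust(pvalue)
  significant <- abs(log2fc) > fc_threshold & fdr < fdr_threshold
  direction <- ifelse(log2fc < 0, "reduced",
                      ifelse(log2fc > 0, "increased", "tie"))
  res <- data.frame(peak = row_ids(x$counts, x$peaks), mean_signal = mean_signal,
                    log2fc = log2fc, pvalue = pvalue, fdr = fdr,
                    significant = significant, direction = direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(res, "dispersion") <- dispersion
  class(res) <- c("acc_diff", "data.frame")
  res
}

#' Three-group omnibus test
#'
#' One-way ANOVA F-test per peak on normalized signal across three groups
#' (e.g. normal / early / late), with BH FDR.  For each adjacent contrast
#' the sign of the group-mean difference is reported.
#'
#' @param x An `acc_counts` or `acc_norm` object.
#' @param groups A list of three disjoint, non-empty sample-id vectors, in
#'   stage order.
#' @param fdr_threshold FDR cut for the `significant` flag (default 0.01).
#' @return A data.frame with columns `peak`, `pvalue`, `fdr`,
#'   `significant`, `dir_2_vs_1`, `dir_3_vs_2` (signs -1/0/+1 of the
#'   group-mean differences).
#' @export
three_group_test <- function(x, groups, fdr_threshold = 0.01) {
  if (inherits(x, "acc_counts")) x <- normalize_counts(x)
  stopifnot(inherits(x, "acc_norm"))
  if (length(groups) != 3L || any(lengths(groups) == 0L)) {
    stop("'groups' must be three non-empty sample-id vectors")
  }
  all_ids <- unlist(groups)
  if (anyDuplicated(all_ids)) stop("groups must be disjoint")
  if (!all(all_ids %in% x$samples$sample_id)) stop("unknown sample id")

  y <- x$values[, all_ids, drop = FALSE]
  g <- factor(rep(seq_along(groups), lengths(groups)))
  n <- length(all_ids)
  k <- 3L
  grand <- rowMeans(y)
  gm <- vapply(levels(g), function(l) rowMeans(y[, g == l, drop = FALSE]),
               numeric(nrow(y)))
  ssb <- rowSums(sweep(gm^2, 2L, table(g), "*")) - n * grand^2
  sst <- rowSums(y^2) - n * grand^2
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1L
  df2 <- n - k
  if (df2 < 1L) stop("need more samples than groups")
  fstat <- (ssb / df1) / (ssw / df2)
  pvalue <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  pvalue[ssw == 0 & ssb == 0] <- 1  # completely constant peak
  fdr <- bh_adjust(pvalue)
  data.frame(peak = row_ids(y, x$peaks),
             pvalue = pvalue, fdr = fdr,
             significant = fdr < fdr_threshold,
             dir_2_vs_1 = sign(gm[, 2L] - gm[, 1L]),
             dir_3_vs_2 = sign(gm[, 3L] - gm[, 2L]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Global accessibility shift summary
#'
#' Summarizes a per-peak fold-change table into the fraction of peaks with
#' reduced accessibility and a mean fold-change-by-intensity curve (the
#' smoothed line of an MA plot).  Peaks with `log2fc < 0` count as reduced
#' and `log2fc > 0` as increased; exact ties form their own category and
#' are excluded from the reduced numerator but kept in the denominator.
#'
#' @param result A data.frame with columns `log2fc` and `mean_signal`
#'   (e.g. from [differential_test()] or [paired_eye_shift()]).
#' @param n_bins Number of equal-width intensity bins for the curve.
#' @return A list of class `global_shift_summary`: `n_peaks`, `n_reduced`,
#'   `n_increased`, `n_tie`, `frac_reduced`, and `mean_fc_curve`
#'   (data.frame `bin_center`, `mean_log2fc`, `n`).
#' @export
global_shift <- function(result, n_bins = 50L) {
  if (nrow(result) == 0L) stop("empty result")
  if (n_bins < 1L) stop("'n_bins' must be >= 1")
  fc <- result$log2fc
  n_reduced <- sum(fc < 0)
  n_increased <- sum(fc > 0)
  n_tie <- sum(fc == 0)
  ms <- result$mean_signal
  rng <- range(ms)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  bin <- cut(ms, breaks, include.lowest = TRUE)
  curve <- data.frame(
    bin_center = (breaks[-1] + breaks[-length(breaks)]) / 2,
    mean_log2fc = as.numeric(tapply(fc, bin, mean)),
    n = as.integer(table(bin))
  )
  structure(list(n_peaks = length(fc), n_reduced = n_reduced,
                 n_increased = n_increased, n_tie = n_tie,
                 frac_reduced = n_reduced / length(fc),
                 mean_fc_curve = curve),
            class = "global_shift_summary")
}

#' @export
print.global_shift_summary <- function(x, ...) {
  cat(sprintf("global shift: %d peaks, %d reduced (%.1f%%), %d increased, %d ties\n",
              x$n_peaks, x$n_reduced, 100 * x$frac_reduced,
              x$n_increased, x$n_tie))
  invisible(x)
}

#' Paired-eye (two-sample) accessibility shift
#'
#' Per-peak signal difference between two samples of the same donor (e.g.
#' left and right macular retina at different disease stages):
#' `log2fc = C_N(left) - C_N(right)`, already library-size normalized, then
#' summarized as in [global_shift()].
#'
#' @param norm An `acc_norm` object.
#' @param left,right Sample ids; fold changes are left minus right.
#' @param n_bins Intensity bins for the curve.
#' @return A `global_shift_summary`.
#' @export
paired_eye_shift <- function(norm, left, right, n_bins = 50L) {
  stopifnot(inherits(norm, "acc_norm"))
  ids <- norm$samples$sample_id
  if (!left %in% ids) stop("unknown sample id: ", left)
  if (!right %in% ids) stop("unknown sample id: ", right)
  fc <- norm$values[, left] - norm$values[, right]
  res <- data.frame(peak = row_ids(norm$values, norm$peaks),
                    mean_signal = (norm$values[, left] + norm$values[, right]) / 2,
                    log2fc = fc, stringsAsFactors = FALSE)
  global_shift(res, n_bins = n_bins)
}

#' Write a differential result as TSV
#' @param result An `acc_diff` data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_diff_tsv <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
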