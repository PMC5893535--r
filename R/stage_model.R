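## Per-peak linear model of normalized accessibility on disease stage and
## confounders:
##   C_N = a0 + a1*stage + a2*region + a3*gender + a4*age + a5*interval + e
## with stage coded 0/1/2 (normal/early/late), region and gender -1/+1.
## All peaks share one design matrix, so a single QR factorization serves
## every fit.

STAGE_DESIGN_COLS <- c("stage_code", "region_code", "gender_code",
                       "age", "interval")

stage_design <- function(samples) {
  missing <- setdiff(STAGE_DESIGN_COLS, names(samples))
  if (length(missing)) {
    stop("metadata missing covariate(s): ", paste(missing, collapse = ", "))
  }
  if (anyNA(samples[STAGE_DESIGN_COLS])) stop("missing covariate values")
  X <- cbind(intercept = 1,
             stage = samples$stage_code,
             region = samples$region_code,
             gender = samples$gender_code,
             age = samples$age,
             interval = samples$interval)
  X
}

#' Fit the per-peak stage model
#'
#' Ordinary least squares of normalized signal on disease stage with
#' covariate adjustment for region, gender, age and procurement interval,
#' fitted independently for every peak.  The stage p-value is the two-sided
#' t-test of the stage coefficient (alpha1); FDR is BH-adjusted across
#' peaks.
#'
#' @param norm An `acc_norm` object.
#' @param samples Optional metadata override (defaults to `norm$samples`).
#' @return A data.frame of class `stage_fit` with columns `peak`,
#'   `alpha0`..`alpha5`, `se0`..`se5`, `sigma2` (residual variance),
#'   `stage_p`, `stage_fdr`.  The peak `GRanges` is kept as attribute
#'   `"peaks"`.
#' @export
fit_stage_model <- function(norm, samples = NULL) {
  stopifnot(inherits(norm, "acc_norm"))
  if (is.null(samples)) samples <- norm$samples
  Y <- norm$values
  n <- nrow(samples)
  p <- 6L
  if (n < p + 1L) stop("need at least ", p + 1L, " samples, got ", n)
  X <- stage_design(samples)
  qrX <- qr(X)
  if (qrX$rank < p) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm.fit(X, t(Y))
  beta <- t(fit$coefficients)              # peaks x 6
  res <- t(fit$residuals)                  # peaks x n
  df <- n - p
  sigma2 <- rowSums(res^2) / df
  xtx_inv <- solve(crossprod(X))
  se <- sqrt(outer(sigma2, diag(xtx_inv)))
  tstat <- beta[, 2L] / se[, 2L]
  stage_p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  stage_p[sigma2 < 1e-20] <- 1   # exact fit / constant peak: no evidence
  out <- data.frame(peak = row_ids(Y, norm$peaks), stringsAsFactors = FALSE)
  for (j in 1:6) out[[paste0("alpha", j - 1L)]] <- beta[, j]
  for (j in 1:6) out[[paste0("se", j - 1L)]] <- se[, j]
  out$sigma2 <- sigma2
  out$stage_p <- stage_p
  out$stage_fdr <- bh_adjust(stage_p)
  attr(out, "peaks") <- norm$peaks
  attr(out, "df") <- df
  class(out) <- c("stage_fit", "data.frame")
  out
}

#' Select differentially accessible regions (DARs)
#'
#' Candidates are peaks with `stage_fdr < fdr_cut` and a negative stage
#' coefficient; they are ranked by the stage coefficient ascending (most
#' strongly negative first, ties broken by smaller FDR, then genomic
#' position) and the top `top_n` are returned.  All remaining peaks in the
#' fitted universe are the non-DARs.
#'
#' @param fits A `stage_fit` table from [fit_stage_model()].
#' @param fdr_cut Stage-FDR cut (default 0.01).
#' @param top_n Maximum number of DARs (default 5000).
#' @return A list of class `dar_set`: `dars` (`GRanges` with `alpha1`,
#'   `stage_fdr`, `rank`), `non_dars` (`GRanges`), `fdr_cut`, `top_n`.
#' @export
select_dars <- function(fits, fdr_cut = 0.01, top_n = 5000L) {
  stopifnot(inherits(fits, "stage_fit"))
  if (nrow(fits) == 0L) stop("empty fit table")
  if (top_n < 1L) stop("'top_n' must be >= 1")
  peaks <- attr(fits, "peaks")
  cand <- which(fits$stage_fdr < fdr_cut & fits$alpha1 < 0)
  ord <- cand[order(fits$alpha1[cand], fits$stage_fdr[cand], cand)]
  take <- utils::head(ord, top_n)
  dars <- peaks[take]
  if (length(take)) {
    dars$alpha1 <- fits$alpha1[take]
    dars$stage_fdr <- fits$stage_fdr[take]
    dars$rank <- seq_along(take)
  }
  non <- peaks[setdiff(seq_len(nrow(fits)), take)]
  structure(list(dars = dars, non_dars = non,
                 fdr_cut = fdr_cut, top_n = top_n),
            class = "dar_set")
}

#' @export
print.dar_set <- function(x, ...) {
  cat("dar_set: ", length(x$dars), " DARs, ", length(x$non_dars),
      " non-DARs (FDR < ", x$fdr_cut, ", top ", x$top_n, ")\n", sep = "")
  invisible(x)
}

#' Write a stage-fit table as TSV
#' @param fits A `stage_fit` table.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_stage_fit_tsv <- function(fits, path) {
  utils::write.table(as.data.frame(fits), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write DARs as BED with a rank column
#' @param dars A `dar_set`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_dars_bed <- function(dars, path) {
  stopifnot(inherits(dars, "dar_set"))
  gr <- dars$dars
  extra <- if (length(gr)) {
    data.frame(rank = gr$rank, alpha1 = gr$alpha1)
  } else NULL
  write_bed(gr, path, extra = extra)
}
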