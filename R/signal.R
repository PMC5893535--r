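## Peak-by-sample signal containers.  Modeled on edgeR's DGEList: a plain
## S3 list holding the matrix, the peak GRanges and the sample metadata,
## so that everything stays subsettable and printable with base tools.

SAMPLE_META_COLS <- c("sample_id", "tissue", "region_code", "stage_code",
                      "gender_code", "age", "interval", "library_size")

## Row identifiers for a signal matrix: rownames when present, else the
## canonical names of the accompanying peaks.
row_ids <- function(m, peaks) {
  if (!is.null(rownames(m))) rownames(m) else peak_names(peaks)
}

validate_sample_meta <- function(samples) {
  if (!is.data.frame(samples)) stop("'samples' must be a data.frame")
  missing <- setdiff(SAMPLE_META_COLS, names(samples))
  if (length(missing)) {
    stop("sample metadata is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  if (anyDuplicated(samples$sample_id)) stop("duplicated sample_id")
  if (any(samples$library_size <= 0)) stop("library_size must be > 0")
  if (!all(samples$stage_code %in% 0:2)) {
    stop("stage_code must be 0 (normal), 1 (early) or 2 (late)")
  }
  if (!all(samples$region_code %in% c(-1, 1))) {
    stop("region_code must be -1 (periphery) or +1 (macula)")
  }
  if (!all(samples$gender_code %in% c(-1, 1))) {
    stop("gender_code must be -1 (female) or +1 (male)")
  }
  invisible(samples)
}

#' Read a sample metadata table
#'
#' Tab-separated with columns `sample_id`, `tissue`, `region_code`
#' (-1 periphery, +1 macula), `stage_code` (0 normal, 1 early, 2 late),
#' `gender_code` (-1 female, +1 male), `age` (years), `interval` (hours
#' from death to tissue procurement) and `library_size` (count of qualified
#' fragments).
#'
#' @param path Path to the TSV.
#' @return A validated data.frame.
#' @export
read_sample_meta <- function(path) {
  samples <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_sample_meta(samples)
  samples
}

#' Assemble a raw count container
#'
#' @param counts Integer matrix, peaks x samples.  Column names must match
#'   `samples$sample_id`; row names default to [peak_names()] of `peaks`.
#' @param peaks `GRanges` of the peak universe, one per matrix row.
#' @param samples Sample metadata data.frame (see [read_sample_meta()]).
#' @return An object of class `acc_counts`: a list with elements `counts`,
#'   `peaks`, `samples`.
#' @export
acc_counts <- function(counts, peaks, samples) {
  counts <- as.matrix(counts)
  validate_sample_meta(samples)
  if (nrow(counts) != length(peaks)) {
    stop("nrow(counts) must equal length(peaks)")
  }
  if (ncol(counts) != nrow(samples)) {
    stop("ncol(counts) must equal nrow(samples)")
  }
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("raw counts must be non-negative integers")
  }
  if (is.null(colnames(counts))) colnames(counts) <- samples$sample_id
  if (!identical(colnames(counts), samples$sample_id)) {
    stop("colnames(counts) must match samples$sample_id")
  }
  rownames(counts) <- peak_names(peaks)
  structure(list(counts = counts, peaks = peaks, samples = samples),
            class = "acc_counts")
}

#' @export
print.acc_counts <- function(x, ...) {
  cat("acc_counts: ", nrow(x$counts), " peaks x ", ncol(x$counts),
      " samples\n", sep = "")
  invisible(x)
}

#' Build a count matrix from per-sample fragment files
#'
#' @param fragment_paths Named character vector of fragment BED paths; the
#'   names are sample ids and must match `samples$sample_id`.
#' @param peaks Consensus peak `GRanges`.
#' @param samples Sample metadata.
#' @return An `acc_counts` object.
#' @export
build_count_matrix <- function(fragment_paths, peaks, samples) {
  validate_sample_meta(samples)
  if (is.null(names(fragment_paths)) ||
      !setequal(names(fragment_paths), samples$sample_id)) {
    stop("'fragment_paths' must be named by sample_id")
  }
  counts <- vapply(samples$sample_id, function(sid) {
    count_fragments(fragment_paths[[sid]], peaks)
  }, integer(length(peaks)))
  acc_counts(counts, peaks, samples)
}

#' Library-size normalization of raw counts
#'
#' Converts raw fragment counts C_R to normalized signal
#' `C_N = log2(C_R / S_L * 1e8 + 1)`, where `S_L` is the per-sample library
#' size (count of qualified fragments).  `C_N` is 0 exactly when `C_R` is 0.
#'
#' @param x An `acc_counts` object.
#' @param library_size Optional name of the metadata column holding the
#'   library size; defaults to `"library_size"`.  Allows an alternative
#'   definition (e.g. properly-paired fragment totals) to be stored as
#'   another column and selected here.
#' @return An object of class `acc_norm` with elements `values` (real
#'   matrix of C_N), `peaks`, `samples`.
#' @export
normalize_counts <- function(x, library_size = "library_size") {
  stopifnot(inherits(x, "acc_counts"))
  sl <- x$samples[[library_size]]
  if (is.null(sl)) stop("no metadata column '", library_size, "'")
  if (any(sl <= 0)) stop("library sizes must be > 0")
  values <- log2(sweep(x$counts, 2L, sl, "/") * 1e8 + 1)
  structure(list(values = values, peaks = x$peaks, samples = x$samples),
            class = "acc_norm")
}

#' Invert the count normalization
#'
#' Recovers raw counts from normalized signal: `C_R = (2^C_N - 1) * S_L / 1e8`.
#'
#' @param norm An `acc_norm` object.
#' @param library_size Metadata column used for `S_L`.
#' @return A real matrix approximating the raw counts.
#' @export
denormalize_counts <- function(norm, library_size = "library_size") {
  stopifnot(inherits(norm, "acc_norm"))
  sl <- norm$samples[[library_size]]
  sweep(2^norm$values - 1, 2L, sl, "*") / 1e8
}

#' @export
print.acc_norm <- function(x, ...) {
  cat("acc_norm: ", nrow(x$values), " peaks x ", ncol(x$values),
      " samples\n", sep = "")
  invisible(x)
}

#' Filter peaks by mean normalized signal
#'
#' Retains peaks whose mean C_N across the given samples is at or above a
#' threshold (boundary inclusive).  The threshold may be a constant (the
#' default 6.5 sits near the 75% quantile of typical peak signal) or the
#' string `"quantile:q"` to use the q-quantile of the per-peak means.
#'
#' @param norm An `acc_norm` object.
#' @param threshold Numeric constant, or `"quantile:q"` (e.g.
#'   `"quantile:0.75"`).
#' @param scope Character vector of sample ids over which the mean is taken;
#'   defaults to all samples.
#' @return An `acc_norm` with the retained peak rows (sample set unchanged).
#' @export
filter_by_mean_signal <- function(norm, threshold = 6.5, scope = NULL) {
  stopifnot(inherits(norm, "acc_norm"))
  if (is.null(scope)) scope <- norm$samples$sample_id
  if (length(scope) == 0L) stop("'scope' must name at least one sample")
  if (!all(scope %in% norm$samples$sample_id)) {
    stop("unknown sample id in 'scope'")
  }
  means <- rowMeans(norm$values[, scope, drop = FALSE])
  if (is.character(threshold)) {
    if (!grepl("^quantile:", threshold)) {
      stop("character threshold must look like 'quantile:0.75'")
    }
    q <- as.numeric(sub("^quantile:", "", threshold))
    if (!is.finite(q) || q < 0 || q > 1) stop("invalid quantile in threshold")
    threshold <- stats::quantile(means, q, names = FALSE)
  }
  keep <- means >= threshold
  structure(list(values = norm$values[keep, , drop = FALSE],
                 peaks = norm$peaks[keep],
                 samples = norm$samples),
            class = "acc_norm")
}

#' Classical multidimensional scaling of samples
#'
#' Torgerson (classical) MDS on the sample-by-sample Euclidean distance
#' matrix of normalized peak profiles.  Deterministic up to sign/rotation
#' of the axes.
#'
#' @param norm An `acc_norm` object.
#' @param dims Number of output dimensions (default 2).
#' @return A samples x `dims` matrix of coordinates, rownames sample ids.
#' @export
classical_mds <- function(norm, dims = 2L) {
  stopifnot(inherits(norm, "acc_norm"))
  n <- ncol(norm$values)
  if (n < dims + 1L) {
    stop("need at least dims + 1 = ", dims + 1L, " samples, got ", n)
  }
  d <- stats::dist(t(norm$values))
  coords <- stats::cmdscale(d, k = dims)
  ## cmdscale drops trailing zero-eigenvalue axes (e.g. duplicated samples)
  if (ncol(coords) < dims) {
    coords <- cbind(coords,
                    matrix(0, nrow = nrow(coords), ncol = dims - ncol(coords)))
  }
  rownames(coords) <- norm$samples$sample_id
  coords
}

#' Write / read a signal matrix as TSV
#'
#' Header row of sample ids, first column `peak` holding the peak name.
#'
#' @param x An `acc_counts` or `acc_norm` object.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_signal_tsv <- function(x, path) {
  m <- if (inherits(x, "acc_counts")) x$counts else x$values
  df <- data.frame(peak = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write sample metadata as TSV
#' @param samples Sample metadata data.frame.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_sample_meta <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
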