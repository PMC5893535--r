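## End-to-end orchestration: count -> normalize -> filter -> MDS/diff ->
## stage model -> DARs -> annotation -> SNP overlap (-> footprinting when
## motifs are provided), with a JSON run manifest.

default_thresholds <- function() {
  list(merge_gap = 10, signal = 6.5, fc = 0.8, fdr = 0.05,
       dar_fdr = 0.01, top_n = 5000, snp_extension = 5000,
       snp_p = 5e-8)
}

#' Read a pipeline configuration
#'
#' YAML with entries `peaks` (BED), `fragments` (map sample_id -> BED
#' path), `metadata` (sample TSV), optional `blacklist`, `motifs`,
#' `genes`, `snps`, optional `groups` (`a`/`b` and optionally `c`,
#' sample-id lists), a `thresholds` map overriding the defaults
#' (`merge_gap` 10, `signal` 6.5, `fc` 0.8, `fdr` 0.05, `dar_fdr` 0.01,
#' `top_n` 5000, `snp_extension` 5000, `snp_p` 5e-8), and `outdir`.
#'
#' @param path Path to the YAML file.
#' @return The configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  thr <- default_thresholds()
  thr[names(cfg$thresholds)] <- cfg$thresholds
  cfg$thresholds <- thr
  cfg
}

pipeline_stage <- function(name, expr) {
  t0 <- Sys.time()
  res <- tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  message(sprintf("[%s] done in %.2fs", name,
                  as.numeric(Sys.time() - t0, units = "secs")))
  res
}

#' Run the full analysis pipeline
#'
#' Executes every configured stage and writes TSV/BED artifacts plus a
#' `manifest.json` recording the package version, a configuration hash and
#' per-artifact row counts.  Outputs are a pure function of inputs and
#' configuration, so a rerun on identical inputs reproduces the manifest.
#'
#' @param config A configuration list (see [read_pipeline_config()]) or
#'   the path to a YAML file.
#' @param outdir Output directory (overrides `config$outdir`).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  thr <- config$thresholds
  if (is.null(thr)) thr <- default_thresholds()
  outdir <- if (!is.null(outdir)) outdir else config$outdir
  if (is.null(outdir)) stop("no output directory configured")
  for (key in c("peaks", "metadata")) {
    if (is.null(config[[key]])) stop("config is missing '", key, "'")
  }
  paths <- c(config$peaks, config$metadata, unlist(config$fragments),
             config$blacklist, config$motifs, config$genes, config$snps)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("configured input(s) not found: ", paste(missing, collapse = ", "))
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- list()
  emit <- function(name, n) artifacts[[name]] <<- n

  samples <- pipeline_stage("metadata", read_sample_meta(config$metadata))

  peaks <- pipeline_stage("peaks", {
    p <- read_intervals(config$peaks)
    p <- merge_proximal(p, gap_lt = thr$merge_gap)
    if (!is.null(config$blacklist)) {
      p <- subtract_blacklist(p, read_intervals(config$blacklist))
    }
    write_bed(p, file.path(outdir, "consensus_peaks.bed"))
    emit("consensus_peaks.bed", length(p))
    p
  })

  counts <- pipeline_stage("count", {
    cm <- build_count_matrix(unlist(config$fragments), peaks, samples)
    write_signal_tsv(cm, file.path(outdir, "raw_counts.tsv"))
    emit("raw_counts.tsv", nrow(cm$counts))
    cm
  })

  norm <- pipeline_stage("normalize", {
    nn <- normalize_counts(counts)
    nn <- filter_by_mean_signal(nn, threshold = thr$signal)
    write_signal_tsv(nn, file.path(outdir, "normalized_filtered.tsv"))
    emit("normalized_filtered.tsv", nrow(nn$values))
    nn
  })
  if (nrow(norm$values) == 0L) {
    stop("pipeline stage 'normalize' failed: no peak passes the signal filter")
  }

  pipeline_stage("mds", {
    if (ncol(norm$values) >= 3L) {
      coords <- classical_mds(norm, dims = 2L)
      utils::write.table(data.frame(sample_id = rownames(coords), coords),
                         file.path(outdir, "mds.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      emit("mds.tsv", nrow(coords))
    }
    NULL
  })

  if (!is.null(config$groups$a) && !is.null(config$groups$b)) {
    pipeline_stage("diff", {
      filt <- acc_counts(counts$counts[rownames(norm$values), , drop = FALSE],
                         norm$peaks, samples)
      res <- differential_test(filt, config$groups$a, config$groups$b,
                               fc_threshold = thr$fc, fdr_threshold = thr$fdr)
      write_diff_tsv(res, file.path(outdir, "differential.tsv"))
      emit("differential.tsv", nrow(res))
      gs <- global_shift(res)
      jsonlite::write_json(gs[c("n_peaks", "n_reduced", "n_increased",
                                "n_tie", "frac_reduced")],
                           file.path(outdir, "global_shift.json"),
                           auto_unbox = TRUE, digits = NA)
      emit("global_shift.json", 1L)
      if (!is.null(config$groups$c)) {
        tg <- three_group_test(filt, list(config$groups$a, config$groups$b,
                                          config$groups$c),
                               fdr_threshold = thr$dar_fdr)
        utils::write.table(tg, file.path(outdir, "three_group.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        emit("three_group.tsv", nrow(tg))
      }
      NULL
    })
  }

  fits <- pipeline_stage("stage_model", {
    f <- fit_stage_model(norm)
    write_stage_fit_tsv(f, file.path(outdir, "stage_fits.tsv"))
    emit("stage_fits.tsv", nrow(f))
    f
  })

  dars <- pipeline_stage("dars", {
    d <- select_dars(fits, fdr_cut = thr$dar_fdr, top_n = thr$top_n)
    write_dars_bed(d, file.path(outdir, "dars.bed"))
    emit("dars.bed", length(d$dars))
    d
  })

  if (!is.null(config$genes)) {
    pipeline_stage("annotation", {
      genes <- read_gene_models(config$genes)
      ann <- annotate_peaks(norm$peaks, genes)
      utils::write.table(ann, file.path(outdir, "peak_annotation.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit("peak_annotation.tsv", nrow(ann))
      ranked <- rank_genes_by_coefficient(fits, ann)
      utils::write.table(ranked, file.path(outdir, "ranked_genes.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit("ranked_genes.tsv", nrow(ranked))
      NULL
    })
  }

  if (!is.null(config$snps)) {
    pipeline_stage("snp_overlap", {
      snps <- read_snps(config$snps)
      sets <- list(dars = dars$dars, non_dars = dars$non_dars,
                   non_peaks = make_nonpeaks(norm$peaks))
      rows <- lapply(names(sets), function(nm) {
        ov <- snp_overlap(sets[[nm]], snps, extension = thr$snp_extension,
                          p_threshold = thr$snp_p)
        data.frame(set = nm, n_regions = ov$n_regions,
                   proportion = ov$proportion, stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, rows)
      utils::write.table(df, file.path(outdir, "snp_overlap.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      emit("snp_overlap.tsv", nrow(df))
      NULL
    })
  }

  if (!is.null(config$motifs)) {
    pipeline_stage("footprint", {
      motifs <- read_motifs(config$motifs)
      ins <- insertions_from_fragments(
        read_fragments(config$fragments[[1L]]))
      fos <- compute_fos(ins, motifs)
      write_fos_tsv(fos, file.path(outdir, "fos.tsv"))
      emit("fos.tsv", nrow(fos))
      if (length(dars$dars) > 0L) {
        enr <- footprint_enrichment(motifs, dars$dars, dars$non_dars)
        utils::write.table(enr, file.path(outdir, "footprint_enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        emit("footprint_enrichment.tsv", nrow(enr))
      }
      NULL
    })
  }

  manifest <- list(
    package = "atacdar",
    version = as.character(utils::packageVersion("atacdar")),
    config_hash = rlang::hash(config),
    artifacts = artifacts
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
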