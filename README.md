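# atacdar

Downstream analysis of bulk ATAC-Seq cohorts, built for studies of
degenerative disease in paired tissues — the motivating setting is
chromatin accessibility in postmortem retina and retinal pigment
epithelium (RPE) across stages of age-related macular degeneration (AMD),
where accessibility shows a broad, stage-graded decrease.  The package
takes fragment intervals and called peaks (everything upstream of that —
alignment, deduplication, peak calling, motif scanning — is left to the
standard tools) and provides, as a tested R API plus a thin command-line
wrapper:

* **Consensus peaks** — proximity merging (gap < 10 bp), blacklist
  removal, any-overlap fragment counting.
* **Signal matrix** — library-size normalization
  `C_N = log2(C_R / S_L × 1e8 + 1)`, mean-signal filtering (≥ 6.5),
  classical MDS of samples.
* **Differential accessibility** — a negative binomial exact test with
  moment-estimated common dispersion (|log2 FC| > 0.8, FDR < 0.05),
  a three-group ANOVA-type test, and global-shift summaries (fraction of
  reduced peaks, fold-change-vs-intensity curve), including paired-eye
  comparisons of single donors.
* **Stage model** — per-peak OLS of normalized signal on disease stage
  with region/gender/age/procurement-interval adjustment
  (`C_N = α0 + α1·stage + α2·region + α3·gender + α4·age + α5·interval + ε`),
  and DAR selection: peaks with stage FDR < 0.01 and α1 < 0, ranked most
  negative first, top 5000.
* **Footprinting** — Tn5 insertion profiles around motifs and the
  footprint occupancy score
  `FOS = min(−log2((N_C+1)/(N_L+1)), −log2((N_C+1)/(N_R+1)))`, with
  hypergeometric footprint-in-DAR enrichment.
* **Annotation** — nearest-gene assignment with promoter/3'UTR/exon/
  intron/intergenic categories, min-coefficient gene ranking, GWAS
  SNP–peak overlap with flanking non-peak controls.
* **Synthetic cohorts** — a ground-truth generator (planted stage
  effects, confounders, NB noise, footprint depths) so every stage is
  testable without sequencing data.

See `vignettes/methods.Rmd` for the models, parameter meanings, and the
design decisions behind each step.

## Worked example

Simulate a 25-sample retina-like cohort (11 normal / 5 early / 9 late)
with stage effects of about −0.4 log2 units planted in 90% of peaks, then
ask the two headline questions — is accessibility globally reduced in
disease, and is the stage coefficient recovered?

```r
library(atacdar)

cfg <- cohort_config(n_peaks = 2000, seed = 7)
sim <- simulate_cohort(cfg)
sim$counts
#> acc_counts: 2000 peaks x 25 samples

s <- sim$counts$samples
res <- differential_test(sim$counts,
                         s$sample_id[s$stage_code == 0],   # normal
                         s$sample_id[s$stage_code > 0])    # AMD
global_shift(res)
#> global shift: 2000 peaks, 1854 reduced (92.7%), 146 increased, 0 ties

fits <- fit_stage_model(normalize_counts(sim$counts))
mean(fits$alpha1)
#> [1] -0.359       # planted mean: -0.359
```

92.7% of peaks show reduced accessibility in the disease group — the
planted 90% of truly reduced peaks plus the null peaks that fall on the
negative side by chance.  The per-peak stage coefficients are recovered
without bias.  The footprint score on its worked fixture (central count 0,
flank totals 21 and 45):

```r
site <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1001, 1010))
ins  <- data.frame(chrom = "chr1", pos = c(rep(975, 21), rep(1025, 45)))
compute_fos(ins, site)
#>             site motif_id N_C N_L N_R fos
#> 1 chr1:1000-1010     <NA>   0   7  15   3
```

A YAML-configured end-to-end run (`run_pipeline("config.yaml")`) writes
consensus peaks, count and normalized matrices, MDS coordinates,
differential tables, stage fits, DAR BED, annotations, SNP overlap and
footprint tables, plus a JSON manifest; `inst/scripts/atacdar.R` exposes
the same stages as shell subcommands.

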