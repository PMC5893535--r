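---
title: "Models and methods behind atacdar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind atacdar}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atacdar)
```

# Scope and data model

`atacdar` analyzes bulk ATAC-Seq cohorts downstream of alignment and peak
calling.  Its inputs are fragment interval files (BED3+, one record per
sequenced fragment), per-sample or pooled peak calls, a blacklist, a sample
metadata table, and optionally motif occurrences, gene models and a GWAS SNP
table.  Everything upstream — trimming, alignment, duplicate removal, peak
calling, motif scanning, footprint detection — is assumed done by standard
tools and is out of scope.

Intervals are held as `GRanges` (1-based, closed), the Bioconductor
convention; BED input and output are 0-based half-open and converted at the
reader/writer boundary.  Chromosome names are matched as exact strings with
no aliasing.

# Consensus peaks and counting

Per-sample peaks are merged into a consensus: any two same-chromosome peaks
whose gap is *strictly* less than 10 bp (configurable) are united,
transitively.  The threshold is strict, so two peaks separated by exactly
10 bp stay separate.  Peaks overlapping a blacklist interval by at least
1 bp are removed whole, not trimmed.

Fragments are counted over the consensus with an any-overlap rule: a
fragment contributes 1 to every peak it overlaps by at least 1 bp.  A
fragment spanning two peaks therefore counts once in each; published
counting tools differ here and no single convention is canonical, so the
simplest well-defined rule was chosen and is stated rather than hidden.

# Normalization and filtering

Raw counts $C_R$ are normalized by the per-sample library size $S_L$ (the
count of qualified fragments):

$$C_N = \log_2\!\left(\frac{C_R}{S_L} \times 10^8 + 1\right)$$

$C_N$ is zero exactly when $C_R$ is zero, and the transform inverts exactly,
which the tests exploit as a round-trip check.  An alternative library-size
definition (e.g. properly-paired fragment totals) can be stored as an extra
metadata column and selected by name — one code path, two definitions.

Weak regions are removed by mean signal: a peak is kept when its mean $C_N$
across the scoped samples is at least 6.5 (boundary inclusive).  In a
typical cohort that constant sits near the 75% quantile of per-peak means,
and `"quantile:0.75"` is accepted as an alternative threshold
specification.

Sample structure is summarized by classical (Torgerson) multidimensional
scaling of the sample-by-sample Euclidean distances of $C_N$ profiles.
Classical scaling is deterministic up to axis sign/rotation; no iterative
variant is used.

# Differential accessibility

## Pairwise test

Counts are modeled as negative binomial.  Counts are scaled to the
geometric-mean library size; a single common dispersion $\phi$
(variance $= \mu + \phi\mu^2$) is estimated by the method of moments: per
peak and group, $(s^2 - \bar y)$ is compared with the unbiased estimate of
$\mu^2$, namely $\bar y^2 - s^2/n$, and per-peak estimates are averaged
with equal weight.  Equal weighting matters: a $\mu^2$-weighted ratio of
sums lets a handful of very strong peaks dominate and is visibly noisier;
with equal weights the estimator is tight enough that the test holds its
nominal size on null data (checked at 1000 peaks against three binomial
standard errors).

The per-peak p-value is a conditional exact test: the sum of $n$ iid
NB$(\mu, 1/\phi)$ counts is NB$(n\mu, n/\phi)$, and conditional on the
two-group total the group-B sum has a distribution free of $\mu$.  The
two-sided p-value sums the probabilities of all outcomes no more likely
than the observed one.  For totals above 20,000 the support is truncated
to a window carrying all but $\sim 10^{-12}$ of the mass, with the excluded
mass added to the p-value (a negligible, conservative correction).  Group
sums of scaled counts are rounded to the nearest integer.

Log2 fold changes use scaled group means with a pseudo-count of 0.5 per
mean, so identical groups give exactly 0 and the statistic is exactly
antisymmetric under group swap.  A peak is significant when
$|\log_2 \text{FC}| > 0.8$ and BH FDR $< 0.05$ (both configurable).  This
test is deliberately in the same family as the quantile-adjusted exact
tests of established count-based packages; on simulated data it agrees
with edgeR's `exactTest` to rank correlation above 0.95, which the suite
checks as an independent cross-validation, not as the implementation.

## Three-group test and global shift

Across normal/early/late groups an omnibus one-way ANOVA F-test is applied
to $C_N$ per peak (FDR $< 0.01$), with the sign of each adjacent group-mean
contrast reported.  An F-test on the log-scale signal is an approximation
to a count-model likelihood ratio; it was chosen because the log-scale
residuals are close to homoscedastic at typical peak intensities.

The global accessibility shift is summarized by the fraction of peaks with
negative log2 fold change.  Exact zeros are reported as ties and excluded
from the reduced numerator but kept in the denominator; at realistic count
depths ties are about 1% of peaks, so the convention barely moves the
fraction, but it is fixed and documented.  The companion curve bins peaks
by mean intensity and reports the mean fold change per bin — the smoothed
line of an MA plot.  For paired eyes of one donor, the same summary is
applied to the per-peak difference $C_N(\text{left}) - C_N(\text{right})$,
which is already library-size normalized.

# The stage model and DARs

Per peak, ordinary least squares fits

$$C_N = \alpha_0 + \alpha_1\,\text{stage} + \alpha_2\,\text{region} +
\alpha_3\,\text{gender} + \alpha_4\,\text{age} +
\alpha_5\,\text{interval} + \varepsilon$$

with stage coded 0/1/2 (normal/early/late), region −1/+1
(periphery/macula), gender −1/+1 (female/male), age in years and
procurement interval in hours.  All peaks share the design matrix, so one
factorization serves every fit.  The stage p-value is the two-sided t-test
on $\alpha_1$, BH-adjusted across peaks.  Two-sided testing followed by a
sign filter was preferred over a one-sided test because the claim being
screened is "significantly negative", and one-sided FDRs would not be
comparable across reanalyses.  Peaks with an exact fit (residual variance
below $10^{-20}$, e.g. constant signal) get p = 1 rather than an
ill-conditioned t ratio.

DARs are the peaks with stage FDR below 0.01 and $\alpha_1 < 0$, ranked by
$\alpha_1$ ascending (most negative first) and truncated to the top 5000.
Ties are broken by smaller FDR, then genomic position, purely for
determinism.  If fewer candidates pass, all of them are returned without
padding.  The remaining fitted peaks are the non-DARs, so DARs and
non-DARs always partition the filtered universe.

Covariate collinearity deserves a note: in a realistic cohort age and
procurement interval differ systematically between stages, which inflates
the standard error of $\alpha_1$.  That is the price of honest covariate
adjustment, and the synthetic generator reproduces it deliberately.

# Footprinting

Tn5 insertion positions are derived from the two ends of each fragment
with the standard +4/−5 correction, applied to the 0-based fragment
boundary coordinates (start, and the exclusive end).  The offsets are
configurable; `(0, -1)` gives the naive first/last covered bases.

The aggregate insertion profile sums per-base insertions in a 200-bp
window centered on each motif occurrence, flipping minus-strand sites so
all sites share the motif orientation, and normalizes by the total
insertions in a 300-bp flanking window.  The flanking window is
interpreted as 150 bp immediately outside each edge of the 200-bp window;
the total width and split are configurable because the geometry admits
more than one reading.  If the flanks contain no insertions the
normalized profile is flagged invalid rather than divided by zero.

The footprint occupancy score for a motif occurrence of length $L$ uses
the central count $N_C$ over the motif span and flank counts over the two
adjacent $3L$ intervals, with $N_L$ and $N_R$ one third of the left and
right flank counts (kept real-valued; the +1 pseudo-counts are applied
after the division):

$$\text{FOS} = \min\!\left(-\log_2\frac{N_C+1}{N_L+1},\;
-\log_2\frac{N_C+1}{N_R+1}\right)$$

Uniform insertion density gives FOS = 0, deeper protection gives larger
positive scores, and central excess gives negative scores.  The
implementation is verified against a brute-force recount of explicitly
enumerated intervals on random fixtures.

Footprint enrichment in DARs is an upper-tail hypergeometric test at the
region level: $k$ footprinted DARs among $K$ footprinted regions, drawn
from $n$ DARs in a universe of $N$ regions.  Counting regions (rather than
sites) keeps the sampling-without-replacement model coherent when a region
hosts several occurrences.  Stratified analyses (gene-proximal vs distal)
are the same test run on the corresponding subsets.  P-values match
exhaustive combinatorial enumeration for universes up to 50 regions.

# Annotation and SNP overlap

Each peak is assigned to the gene whose body is closest to the peak
midpoint (ties to the lexicographically first gene id), then categorized
with a fixed precedence: promoter-proximal (within 2 kb of the TSS or
overlapping a 5'UTR) > 3'UTR (overlapping the 3'UTR or within 2 kb of the
TES) > exonic > intronic > intergenic.  The precedence is a design choice:
the category list is standard but no ordering is canonical, and without
one a peak near a TES inside an exon would be ambiguous.  Gene-level
ranking takes the minimum $\alpha_1$ over a gene's proximal peaks (within
2 kb of the gene body), most negative first — suitable as input to
external gene-set enrichment tools.

For GWAS overlap, each region (optionally extended by ±5 kb) receives the
minimum association P over the SNPs it contains, defaulting to 1 when it
contains none, and the proportion of regions below a threshold is
reported.  Control regions ("non-peaks") are same-width flanks immediately
downstream of each peak (side configurable), skipped when they would
collide with another peak.

# The synthetic cohort generator

The generator exists so that every stage of the pipeline can be tested
against known ground truth without any sequencing data.  Expected counts
follow

$$\mu_{ij} = \frac{S_{L,j}}{10^8}\, 2^{\,\alpha_{0i} + \alpha_{1i}\,
\text{stage}_j + \alpha_2\,\text{region}_j + \alpha_3\,\text{gender}_j +
\alpha_4\,\text{age}_j + \alpha_5\,\text{interval}_j}$$

so the library-size normalization recovers the linear predictor up to the
+1 pseudo-count and parameter-recovery tests are meaningful rather than
circular.  Noise is negative binomial with a single dispersion; a
lognormal–Poisson alternative with matched variance is available to check
that conclusions do not hinge on the exact noise family.

Default conditions describe a plausible postmortem retina cohort:
25 samples (11 normal, 5 early, 9 late) with macula/periphery and
male/female splits mirroring a realistic design; ages and procurement
intervals drawn uniformly from per-stage ranges (ages roughly 79–94,
intervals longer for normal donors than for patients — which makes age and
interval genuinely confounded with stage, as in real cohorts); library
sizes uniform in 20–50 million; baseline signal $\alpha_0 \sim
N(7.5, 1.2)$, above the 6.5 retention threshold; stage effects
$\alpha_1 \sim N(-0.4, 0.1)$ in 90% of peaks and 0 in the rest; mild
confounder coefficients (macula −0.1, gender +0.02, age −0.005/yr,
interval −0.02/h); NB dispersion 0.16, i.e. a biological coefficient of
variation of 0.4, typical for human bulk cohorts.  These defaults were
fixed from the cohort description and field-typical values, not adjusted
to test outcomes.

What the generator does *not* emulate: sequence content, GC or insert-size
bias, peak-width heterogeneity, correlated (paired-donor) noise, and
genome-scale peak counts.  Passing recovery tests therefore demonstrates
statistical correctness of the estimators under the stated model, not
end-to-end fidelity to any particular sequencing experiment.  One
consequence worth knowing: at these default noise levels only a small
fraction of peaks reaches stage FDR < 0.05 with 25 samples, so DAR lists
on default synthetic cohorts are short; real datasets with hundreds of
counts per peak and tens of thousands of peaks have materially more
power.

Fragment simulation places Poisson numbers of fragments uniformly across
each peak (lengths from a sub-nucleosomal 60–120 bp / mono-nucleosomal
180–250 bp mixture) plus uniform background; footprint simulation draws
per-base Poisson insertions at a flank rate and a center rate reduced by
the occupancy, with the closed-form FOS expectation
$\min_s -\log_2\{(r_c L + 1)/(r_s L + 1)\}$ returned for comparison.

# Numerical choices and problem sizes

All randomness flows from explicit integer seeds; generators are
bit-reproducible.  BH adjustment is delegated to `stats::p.adjust` and
checked against a hand-rolled step-up oracle; hypergeometric tails use
`stats::phyper` checked against enumeration; classical MDS uses
`stats::cmdscale`.  The test suite runs cohorts of 500–2000 peaks and
12–25 samples, sizes at which every statistical check (type-I error,
bias, coverage, planted-fraction recovery) has comfortable sampling
precision while the whole suite completes in well under a minute.

# Known limitations

* The exact test rounds scaled group sums; at very low counts (< ~10 per
  group) discreteness makes it mildly conservative.
* The three-group test is a log-scale ANOVA, not a count-model LRT.
* Nearest-gene assignment uses the peak midpoint and gene bodies; it does
  not reproduce any specific annotation tool bit-for-bit.
* Paired eyes from one donor are modeled as independent samples in the
  stage regression (no mixed effects), matching the simple-OLS design.
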