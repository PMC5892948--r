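---
title: "Models and methods behind ribodens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ribodens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ribodens)
```

# The experimental design this package analyses

ribodens analyses ribosome-profiling experiments that probe how stress-induced
eIF2 phosphorylation (the integrated stress response) reshapes mRNA
translation. The design it expects has three biological replicates of two
conditions — untreated and a stressor such as tunicamycin — each assayed three
ways:

* **poly(A) RNA-seq**, measuring transcript abundance;
* **CHX-stabilised footprints**: cycloheximide freezes elongating ribosomes,
  so ~30-nt protected fragments tile translated ORFs;
* **Ht-stabilised footprints**: harringtonine traps initiating ribosomes while
  elongating ones run off, so fragments pile up at translation initiation
  sites (TIS).

All coordinates are transcript-space, 0-based and half-open. The package
consumes aligned 5'-end coverage (bedGraph per sample) plus a transcript-space
GTF and FASTA; read trimming and alignment are upstream of it. One reference
transcript represents each gene; since annotations rarely say which isoform a
"reference transcript" is, the default picks the longest CDS with ties broken
by transcript id (`reference_rule` in `load_annotation()` switches to
first-listed order).

## The -13 offset convention

In these libraries the footprint 5' end sits predominantly 13 nt (minority
12 nt) upstream of the codon being decoded, which places most read starts in
frame 3 relative to the start codon. The package deliberately does **not**
offset-correct when partitioning reads into 5'UTR/CDS/3'UTR: a read whose
ribosome sits on the start codon has its 5' end at -13 and is counted as
5'UTR, so the first four protected codons of the CDS contribute to the 5'UTR
count. This mirrors the upstream analysis convention the counts are meant to
reproduce and keeps the partition a pure function of raw 5'-end positions.
Reads starting inside the stop codon remain CDS (the CDS interval is closed
on the stop codon); whether such reads should be excluded is genuinely
ambiguous, and the simple convention is retained.

# Differential ribosome density

Ribosome density — footprint counts relative to RNA abundance — is a proxy
for translation efficiency. Per gene, the package fits a negative-binomial
log-linear model to the combined RNA and footprint CDS counts:

$$\log \mu = \log L_s + \beta_0 + \beta_{\mathrm{rep}} +
  \beta_{\mathrm{cond}} + \beta_{\mathrm{assay}} +
  \beta_{\mathrm{cond \times assay}}$$

with $L_s$ the per-sample library size. The condition-by-assay interaction is
the quantity of interest: it measures how footprint counts respond to
treatment *beyond* the RNA response, i.e. the change in ribosome density.
It is tested with a likelihood-ratio chi-squared test (1 df) against the
model without the interaction; the LRT is the better-calibrated small-sample
choice here. Replicate enters as a fixed blocking factor (2 df at n = 3),
matching a design where replicates were processed on separate days.

## Filters

Before fitting, genes are filtered on raw counts: (a) at least half of all
samples (RNA and footprints pooled) must have >= 10 reads; (b) mean RNA
count >= 10; (c) mean footprint count >= 4. The pooled reading of (a) was
chosen because the mean filters are described as an *additional* step; the
assay-specific means then guard against poly(A)-selection artifacts
(non-polyadenylated transcripts such as histones are depleted in RNA-seq and
would masquerade as translationally regulated).

## Dispersion estimation and shrinkage

With six residual degrees of freedom per gene, gene-wise NB dispersions are
barely estimable, so they are moderated: each gene's adjusted profile
likelihood (Cox-Reid corrected, evaluated on a log-spaced grid with the
fitted means held at their working values) is augmented with the across-gene
average weighted so the shared curve counts for `prior_df` residual degrees
of freedom (default 10, i.e. weight `prior_df / 6` per gene). The common
dispersion maximises the average curve; the shrunk gene-wise value maximises
the weighted sum, refined by quadratic interpolation in log-dispersion.

Setting `dispersion = 0` gives the exact Poisson limit (verified in the test
suite against an independent `stats::glm` Poisson fit to 1e-6 relative
error); a supplied numeric fixes the dispersion instead of estimating it.

**Known limitation.** When true dispersions are strongly heterogeneous
(e.g. gamma-distributed with a heavy right tail), shrinkage toward a single
common value underestimates the dispersion of the most variable genes and
the LRT becomes mildly anticonservative for them — the familiar behaviour of
NB-LRT pipelines without quasi-likelihood moderation. Calibration is tested
at a constant dispersion of 0.05; with gamma-tailed dispersions the
empirical FDR at a nominal 1% is nearer 5%.

Descriptive fold-changes are reported as
$\log_2((\bar{\mathrm{CPM}}_{tm} + 0.5)/(\bar{\mathrm{CPM}}_{untr} + 0.5))$;
the 0.5-CPM pseudo-count protects the log only in these descriptive columns,
never in the GLM. Genes are classed up/down at Benjamini-Hochberg FDR < 1%
by default.

# TIS peak calling

Ht coverage is pooled over the three replicates of one condition before peak
calling — initiation peaks are sparse and pooling is what gives the rules
their intended scale. A position $p$ with 6-codon window
$W(p) = [p, p + 18)$ is called a peak iff:

1. count$(p)$ > 40% of the coverage in $W(p)$;
2. coverage in $W(p)$ >= 20;
3. no single position in $[p+3, p+18)$ exceeds count$(p)$;
4. count$(p)$ >= 10% of the highest candidate passing 1-3 on the transcript;
5. $p$ lies within 500 nt of the annotated CDS interval.

The denominator in rule 1 is the candidate's own window: the only window the
procedure names is "the following five codons", and a transcript-wide
denominator would make rule 4 redundant. Because the -13/-12 offset split
divides one initiation event over two adjacent positions, surviving
candidates within 1 nt are merged to the higher-count position (ties go
upstream). A consequence of rules 1+2 worth knowing: no peak can have fewer
than 9 reads.

## Codon assignment

The stalled ribosome's P-site codon is probed at +13, then +12, then +14
from the peak; the first AUG/CUG/GUG/UUG wins and sets the offset. If none
is found, the codon at +13 is reported with `canonical = FALSE`. Peaks are
classed by codon position into 5'UTR, annotated start, CDS, or 3'UTR.

## Arginine/lysine artifacts

Harringtonine produces spurious peaks at codons for the large, positively
charged residues arginine and lysine. Non-canonical peaks on those codons
are flagged, and `filter_artifacts()` removes them unless CHX shows an
initiation-like accumulation at the same position. "Accumulation" is
deliberate: CHX libraries carry elongation background along the entire CDS,
so the test requires both a minimum pooled CHX count (default 1) and a
>= 5-fold enrichment over the transcript's average density in the 3-nt
window — a zero-coverage position always fails, an expressed transcript's
flat background also fails, and a genuine pause/initiation site passes.
Canonical peaks are never removed.

# TIS switching

For genes with two or more called TIS (union over conditions, positions
matched within 1 nt), per-replicate counts at each TIS (summing the -13 and
-12 offset positions) are modelled with a Poisson log-linear model:
library-size offset, replicate block, TIS, condition, and TIS-by-condition
interaction. The interaction — "does treatment change the ratio between
initiation sites?" — is tested by a chi-squared LRT on $n_{TIS} - 1$ df and
BH-adjusted at 5%. A random replicate intercept would add an extra variance
parameter that three replicates cannot support, so replicate is a fixed
blocking factor; the model comparison (with vs without the interaction) is
unchanged by this choice.

# ORF classification

Each TIS is extended in-frame to the first UAA/UAG/UGA (no readthrough
model) and classified against the annotated CDS by a total decision table:
upstream ORFs stopping before the CDS (`uorf`); out-of-frame upstream ORFs
running into the CDS (`overlapping_uorf`); in-frame upstream starts with no
intervening stop (`n_terminal_extension`); the annotated start; in-frame and
out-of-frame internal starts; and 3'UTR ORFs. `chx_support()` reports the
ratio of mean CHX 5'-end density inside the ORF to the transcript mean —
a descriptive quantity (uniform coverage gives 1); no threshold declares an
ORF "translated" because none is defensible in general.

The association between regulation class (up / down / control, the control
set being genes with differential-density FDR > 0.5) and the presence of a
canonical 5'UTR TIS in both conditions is tested with Pearson's chi-squared
on the 3 x 2 table (df = 2), with a Fisher fallback when any expected cell
drops below 1.

# The synthetic data generator

`simulate_experiment()` is first-class, tested code that emulates the study
design so every stage is exercisable without sequencing data. What it
emulates, with defaults chosen to match the study where stated:

* 3 replicates x 2 conditions x 3 assays; per-sample library sizes uniform
  in 1e5-1e6 reads;
* NB counts: RNA means proportional to log-normal abundances; footprint
  means additionally scaled by translation efficiency and the planted
  interaction effect (treated samples only); gamma-distributed gene-wise
  dispersions with mean 0.05; multiplicative log-normal (replicate, assay)
  batch effects. Footprint output is normalised by the *untreated* total in
  both conditions, so a planted effect is a true fold change in footprint
  production and compositional shifts surface in the realized library sizes
  — exactly as in a sequencing run with total-count normalisation;
* 5' ends at -13 (80%) / -12 (20%) of the decoded codon, with 10% uniform
  positional noise — reproducing the frame-3 dominance; footprint lengths
  29-33 nt, modal 30-32;
* CHX reads spread over ORF codons with a 5-fold weight on the start codon
  (scanning complexes still reach start codons under CHX, so reads
  accumulate there); uORFs translated in proportion to planted weights;
* Ht reads at TIS positions only (plus a 1% run-off noise floor), in
  proportion to site weights, with the 5'-most TIS getting a 2-fold
  accumulation bias — the drug lets scanning continue, so the first site
  keeps growing. No quantitative value for this bias is reported anywhere,
  so 2 is a package choice;
* planted regulation: 5% up / 10% down by default, |log2| effects in
  [0.5, 2] — about the regulated fraction the headline analysis reports;
* planted TIS switching (uORF weight x 3 under treatment for 5% of
  uORF-bearing genes) and arginine/lysine artifact sites whose Ht reads
  scale with the gene's expression (absolute-count spikes would always fail
  the relative-height rule on expressed genes).

What it does **not** emulate: sequencing error, ligation/adapter bias, rRNA
contamination, isoform mixtures, genome-space alignment artifacts, and any
correlation between uORF presence and regulation (they are planted
independently). Passing tests on this generator therefore demonstrate the
statistical machinery and the rule implementations, not robustness to those
real-data phenomena.

Determinism: every generator function seeds R's RNG from `cfg$seed` (the
counts stage derives its stream by a fixed offset), so equal seeds give
bit-identical FASTA/bedGraph/TSV outputs; the pipeline writes no timestamps,
making whole output directories checksum-stable.

# Numerical choices

* NB GLMs are fitted by Fisher scoring with step-halving, relative
  log-likelihood tolerance 1e-10, coefficients bounded via a +/-50 cap on
  the linear predictor; all-zero responses return NA coefficients and are
  excluded (with a warning) from the BH family.
* The dispersion grid spans 1e-4 to 5 in 25 log-spaced points; grid maxima
  are refined by one quadratic interpolation step.
* LRT statistics are clamped at 0 (they can go microscopically negative at
  convergence tolerance).
* Peak merging is greedy by descending count with upstream tie-break;
  windows truncate at the transcript end.
* Result TSVs render floats at 6 significant digits; library sizes and
  counts are integers and written exactly.

# Problem sizes used in the checks

The test suite runs the calibration study at 300 genes x 200 seeds
(constant dispersion 0.05), parameter recovery at 3000 genes with 200
planted effects per effect size, switching power/calibration at 100 seeds,
and the end-to-end demo at 60-100 genes — sizes at which every Monte-Carlo
tolerance used has comfortable slack while the whole suite stays in a few
minutes on one core.
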