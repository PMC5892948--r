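# ribodens

Differential ribosome density and translation-initiation-site analysis for
ribosome profiling of stress-response experiments.

## The problem

When eIF2 is phosphorylated (the integrated stress response, induced e.g. by
tunicamycin), bulk translation initiation drops while specific transcripts —
classically those regulated through upstream open reading frames (uORFs)
such as *Atf4* — are translated *more*. Dissecting this requires three
parallel measurements per condition: RNA-seq (transcript abundance),
cycloheximide-stabilised ribosome footprints (elongating ribosomes along
ORFs) and harringtonine-stabilised footprints (initiating ribosomes stalled
at start codons). ribodens is the analysis layer for such a design: it takes
transcript-space annotation (GTF + FASTA) and per-sample footprint 5'-end
coverage (bedGraph) and answers, per gene:

* Did ribosome density change under stress? Per gene it fits the
  negative-binomial GLM

  `counts ~ replicate + condition * assay, offset = log(library size)`

  where the **condition x assay interaction** is the change in footprint
  counts beyond the RNA change — i.e. the change in translation efficiency.
  Gene-wise NB dispersions are shrunk toward a common value
  (adjusted-profile-likelihood weighting, prior weight `prior_df = 10`),
  the interaction is tested by a 1-df likelihood-ratio test, and genes are
  called up/down at Benjamini–Hochberg FDR < 1%.
* Where does initiation start? TIS peaks are called from condition-pooled
  harringtonine coverage by five rules (>40% of the 6-codon window in the
  first position; window coverage >= 20; no higher position in the next 5
  codons; >= 10% of the strongest candidate; within 500 nt of the CDS),
  start codons are assigned at +13/+12/+14 from the peak (AUG/CUG/GUG/UUG
  preferred), and spurious arginine/lysine peaks without CHX support are
  removed.
* Does treatment shift usage *between* TIS of one gene? A Poisson GLM on
  per-replicate peak counts tests the TIS x condition interaction (LRT,
  BH 5%).
* What do the TIS encode? Each is extended to its in-frame stop and
  classified: uORF, overlapping uORF, N-terminal extension, internal
  (in/out of frame) ORF, 3'UTR ORF; and the association between 5'UTR TIS
  presence and regulation class is tested with Pearson's chi-squared.

A fully tested synthetic generator (`simulate_experiment()`) emulates the
whole design — 3 replicates x 2 conditions x 3 assays, -13/-12 footprint
offsets, frame-3 dominance, planted translation effects, uORFs, TIS
switching and Ht artifacts — so the pipeline is testable end-to-end without
sequencing data.

## Worked example

```r
library(ribodens)

cfg <- sim_config(n_genes = 120, seed = 42, frac_uorf = 0.4,
                  frac_tis_switch = 0.15)
res <- run_pipeline(pipeline_config(outdir = "demo_out", seed = 42,
                                    sim = cfg))

head(res$diff[order(res$diff$p_value), ], 5)
```

```
    gene_id log2fc_rfp log2fc_rna interaction_log2  p_value      fdr reg_class
100   g0100      -1.90     0.0444            -1.95 6.48e-08 7.77e-06      down
92    g0092      -1.77     0.0730            -1.84 3.06e-07 1.84e-05      down
5     g0005      -1.60     0.5233            -2.13 3.49e-06 1.40e-04      down
85    g0085      -1.44    -0.0326            -1.41 4.38e-05 1.31e-03      down
46    g0046      -1.77    -0.2020            -1.52 2.08e-04 4.99e-03      down
```

Each row is one gene: `log2fc_rfp` / `log2fc_rna` are descriptive CPM
fold-changes (treated over untreated) in footprints and RNA,
`interaction_log2` is the fitted change in ribosome density (here ~ -2:
footprints drop four-fold relative to RNA), and `reg_class` applies the
FDR < 1% cut — 5 of 120 genes are called down, 0 up, matching this seed's
planted truth direction for the strongest effects. The TIS stage called
peaks at all 120 annotated starts plus 49 5'UTR TIS, classified the latter
as uORFs, and flagged the planted switching genes:

```r
table(res$tis_untr$region)
#> annotated_start            utr5
#>             120              49
head(res$switch[order(res$switch$p_value), ], 3)
#>    gene_id n_tis lrt_stat df   p_value       fdr significant
#> 32   g0085     2     1125  1 1.28e-246 6.26e-245        TRUE
#> 34   g0091     2      548  1 2.76e-121 6.77e-120        TRUE
#> 17   g0046     2      445  1  1.00e-98  1.64e-97        TRUE
```

Every stage also writes a TSV into `demo_out/` (`diff_density.tsv`,
`tis_peaks_*.tsv`, `tis_switching.tsv`, `orf_records_*.tsv`,
`tis_association.tsv`, QC and metagene tables) together with a config
snapshot and a run log; reruns with the same seed are bit-identical.
`inst/scripts/run_pipeline.R` wraps the same call for shell use.

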