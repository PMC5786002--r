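# methylseg

Segmentation and regulatory-region analysis of whole-genome bisulfite
sequencing (WGBS) methylomes.

Somatic methylomes are polarized — most CpGs are either highly methylated
or nearly unmethylated — and the deviations from that polarization carry
regulatory meaning. `methylseg` partitions a methylome into the standard
region taxonomy and runs the downstream analyses that taxonomy supports:

* **Segmentation** — partially methylated regions (PMRs) are detected from
  a 101-CpG sliding *disorder score* (the fraction of window CpGs with
  intermediate methylation) decoded by a two-state Gaussian-emission HMM;
  after PMR masking and 3-CpG smoothing, maximal runs of ≥ 3 CpGs with
  smoothed mCpG ≤ 50% become hypomethylated regions, split at 30 CpGs into
  CpG-poor **LMRs** (enhancer-like, 10–50% mCpG) and CpG-rich **UMRs**
  (promoter-like, near 0% mCpG). Detection parameters are justified by a
  shuffle test: the false discovery rate is the region count in a
  position-permuted methylome over the count in the original, required to
  stay below 5%.
* **Annotation** — genic UMRs (gUMRs: TSS-overlapping UMRs clipped to the
  gene, CpG-island CpGs removed, ≥ 10 CpGs), extended-demethylation gene
  flags (gUMR ≥ 5 kb and/or ≥ 25% of the gene), fully methylated regions
  (FMRs, the genomic complement), and ≤ 10 kb gene proximity.
* **Differential methylation** — replicate-aware region tests
  (Mann–Whitney on pooled per-CpG, per-sample levels; significant at
  |Δ mCpG| > 10% and p ≤ 0.001), with the published coverage and
  replicate filters (CpG covered in all samples; replicates with median
  coverage ≤ 4 excluded; PMRs ≥ 75% inside a single gene removed).
* **Chromatin marks** — geometric-mean normalization of coverage tracks,
  promoter (TSS ± 1 kb) or genic (TSS–TES) quantification by mark,
  log-scale mark averaging, and regression of expression-change rank on
  mark ratios.
* **SNP enrichment** — fold enrichment of trait-associated SNPs in LMRs
  against length-matched random region sets, with chi-squared and
  empirical significance.
* **Synthetic data** — seeded generators for every input (methylomes with
  planted segment classes, replicate groups with planted differences,
  coupled mark tracks, enriched SNP sets), so all of the above is testable
  offline with known ground truth.

See the methods vignette
(`vignettes/methylome-segmentation-methods.Rmd`) for the models, the
parameter defaults and the reasoning behind every numerical choice.

## Worked example

Simulate a 5 Mb methylome (~50,000 CpGs at 30× coverage, with planted
PMR/LMR/UMR/CpG-island segments), segment it, and calibrate the detection
parameters by randomization:

```r
library(methylseg)

lay <- simulate_genome_layout(seed = 7)
sim <- simulate_methylome(lay, mean_coverage = 30, seed = 8)
seg <- segment_methylome(sim$methylome, seed = 9, calibrate = TRUE,
                         grid = data.frame(min_cpgs = 3, max_meth = 0.5))

sim$methylome
#> <methylome> synthetic: 50314 CpGs on 1 chromosome(s)
#>   mean level 0.691, median coverage 30

seg$calibration
#> <fdr_calibration> chosen parameters:
#>  min_cpgs max_meth n_original n_randomized         fdr
#>         3      0.5        126            1 0.007936508

table(seg$segments$class)
#> LMR UMR
#> 116  10

head(seg$segments[seg$segments$class == "UMR", ], 3)
#>    chrom   start     end class n_cpg  mean_meth
#> 15  chrS  696656  700439   UMR    63 0.03588391
#> 16  chrS  741172  744705   UMR    63 0.03672613
#> 38  chrS 2384714 2388753   UMR    56 0.04898649
```

The methylome carries 10 planted UMRs, 120 planted LMRs and 8 PMR blocks
covering 40% of the chromosome; the segmentation recovers 10 UMRs and 116
LMR calls (10 detected PMRs covering 40.5%), and the shuffle-estimated
false discovery rate of hypomethylated-region detection at the standard
parameters (≥ 3 CpGs, mCpG ≤ 50%) is 0.8% — comfortably below the 5%
bound. The UMR rows show what the classes mean in numbers: ~60 CpGs per
region at ~4% methylation, versus LMRs at ~8 CpGs and ~30%.

Downstream stages consume the segment table directly, e.g.

```r
gumrs <- assign_gumrs(seg$segments[seg$segments$class == "UMR", ],
                      genes, cgis, sim$methylome)
flags <- flag_extended_demethylation(gumrs)
dmrs  <- region_dmr_test(seg$segments, group_a, group_b)
```

or run end to end from a single YAML config with `run_pipeline()`.

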