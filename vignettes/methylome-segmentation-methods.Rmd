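---
title: "Methods: methylome segmentation and regulatory-region analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: methylome segmentation and regulatory-region analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methylseg)
```

## The problem

Whole-genome bisulfite sequencing (WGBS) measures, at every CpG dyad, the
fraction of reads carrying a methylated cytosine. A typical somatic
methylome is *polarized*: most CpGs are either highly methylated (gene
bodies, intergenic background) or nearly unmethylated (promoters, CpG
islands, active enhancers). Against this background, three region classes
carry most of the regulatory signal:

* **PMRs** (partially methylated regions): large domains of disordered,
  intermediate methylation associated with silent chromatin;
* **UMRs** (unmethylated regions): CpG-rich regions of near-zero
  methylation spanning at least 30 CpGs, typically promoters and the 5'
  ends of actively demethylated genes;
* **LMRs** (low methylated regions): short, CpG-poor regions at 10–50%
  methylation, the footprint of distal cis-regulatory elements.

`methylseg` segments a pooled methylome into these classes, derives genic
UMRs (gUMRs) and the fully methylated complement (FMRs), tests
replicate-aware differential methylation over predefined regions, relates
chromatin-mark signal to expression changes, and tests whether
disease-associated SNPs concentrate in LMRs. A seeded synthetic-data
generator produces every input with known ground truth, so each guarantee
is testable offline.

## Segmentation model

### Disorder score

For each CpG, a centered sliding window of 101 CpGs (step 1) is scored by
the fraction of member CpGs whose methylation level falls strictly inside
an open interval around the polarization antimode, default `(0.3, 0.7)`.
Polarized methylomes place little mass there; PMRs, whose levels are
spread broadly, place much more.

The interval is a tunable parameter (`segmentation_params(disorder_bounds=)`).
The default deserves a note: a wide band such as `(0.1, 0.9)` looks
natural but performs poorly at realistic coverage, because binomial
sampling noise pushes a large share of highly methylated CpGs (true level
~0.85) into the band. Under the generator's fully methylated class
(Beta(17, 3) latent levels, 30x coverage) about 64% of background CpGs
fall inside `(0.1, 0.9)` versus about 78% inside PMRs — a contrast of
0.14 against a window-mean noise sd of ~0.045, which produces state
flicker and boundary smear. The `(0.3, 0.7)` band has a background rate
of ~0.12 versus ~0.40 inside PMRs, and the segmentation sharpens
accordingly. Both bounds remain configurable.

### Two-state HMM

The score track of each chromosome is modeled by a two-state hidden
Markov model with Gaussian emissions, fit by EM (means initialized at the
25th/75th score percentiles, convergence at a log-likelihood change
below 1e-4 or 100 iterations) and decoded by posterior state probability
(Viterbi available by flag). Maximal runs of the high-score state are
PMRs; runs separated by fewer than one disorder window of CpGs are fused,
one window being the resolution limit of the score. Region coordinates
span the first to the last member CpG dyad, half-open.

Two guards apply. When EM degenerates (vanishing variance, empty state)
the decoder falls back to a fixed 0.5 score threshold with a warning. And
a two-state fit is only accepted when it beats a single-Gaussian fit by
the BIC penalty for its four extra parameters; without this, EM happily
splits unimodal noise into two states and calls spurious domains on
chromosomes that contain no PMR at all.

### Masking, smoothing, detection, classification

CpGs inside PMRs are masked. Remaining levels are smoothed with a running
window of three CpGs — the CpG and its immediate non-masked neighbors,
coverage-weighted (unweighted by flag), truncated at chromosome and mask
boundaries so information never crosses a PMR. Hypomethylated regions are
maximal runs of at least 3 consecutive CpGs with smoothed level at most
50%; the region mean is the coverage-weighted mean of raw levels. Regions
with at least 30 CpGs are UMRs, the rest LMRs — the partition is
exhaustive and exclusive. Per-stage segmentations are merged by interval
union within each class family, and merged hypomethylated intervals are
re-classified by their CpG count in the union methylome.

### FDR calibration by methylome randomization

Detection parameters (minimum CpGs, methylation cutoff) are justified by
a shuffle test: regions are counted on the masked, smoothed methylome and
on a randomized copy, and the false discovery rate is estimated as
`randomized / original` (defined as 1 when the original count is zero).
The default pair (3 CpGs, 50%) is accepted when its FDR is below 5%;
otherwise the least stringent passing grid point is chosen, and an error
names the best achieved FDR when nothing passes.

The randomized copy permutes the per-CpG observations of the masked,
*smoothed* methylome across each chromosome's fixed positions. The
alternative — permuting raw observations and re-smoothing — was examined
and rejected: re-smoothing a permuted methylome convolves unrelated
single-CpG observations (a stray near-zero island CpG between two
moderately methylated background CpGs) into composite sub-cutoff values
that exist in neither the original nor the randomized data, so the null
count measures an artifact of the smoothing filter rather than the chance
of spatial clustering of genuinely hypomethylated measurements. Permuting
the detector's actual input preserves its marginal distribution exactly
while destroying all spatial structure, which is the null the FDR is
meant to embody. `randomize_methylome()` (raw-observation permutation per
chromosome) remains available as a general utility.

## Region annotation

* **gUMRs**: for each gene whose genic extent spans at least 1.5 kb
  outside CpG islands, the UMRs containing the TSS (single-base test,
  `start <= tss < end`) are intersected with the genic extent
  `[min(tss, tes), max(tss, tes))` and island intervals are subtracted;
  the result is kept when at least 10 non-island CpGs remain. Fragments
  of one gene form a single logical unit with lengths summed, since all
  downstream criteria are per-gene.
* **Extended demethylation**: a gene is flagged when its gUMR spans at
  least 5 kb and/or covers at least 25% of the gene. The flag is monotone
  in the gUMR.
* **FMRs**: the per-chromosome complement of islands, LMRs, UMRs and
  PMRs, so the five classes tile the genome exactly.
* **Gene proximity**: a region maps to the gene minimizing the distance
  from region boundary to genic extent, within 10 kb; ties break by TSS
  distance, then lexicographic gene id.

## Differential methylation

Replicates with a median CpG coverage of 4 or less are excluded. PMRs
overlapping a single gene to at least 75% are removed before testing
(genic regions downstream of gUMRs are often partially methylated, and
such PMRs would mostly re-measure expression-coupled gene-body
methylation). Per region, only CpGs covered in every retained sample of
both groups enter the statistic; group means are coverage-weighted; the
p-value comes from a two-sided Mann–Whitney rank-sum test on the pooled
per-(CpG, sample) levels. The rank-sum was chosen because the
predefined-region test of the reference tool family is rank-based and
distribution-free; a Welch t on per-sample region means is available by
flag for sensitivity analysis. A region is significant at an absolute
difference above 10% and p at most 0.001, with no multiple-testing
correction gating significance (a Benjamini–Hochberg q-value column is
emitted for transparency). Regions with fewer than 3 kept CpGs are
reported untestable with p = 1 rather than tested, mirroring the 3-CpG
detection floor and avoiding rank-test degeneracy.

The pooled rank-sum treats (CpG, sample) values as exchangeable units.
Under the generator's null — a latent methylation landscape shared by all
replicates, with independent per-CpG beta-binomial replicate noise —
group labels are exchangeable, and the joint rule (p-gate and 10%
effect-size gate) is conservative; the test suite checks a type-I rate at
most twice the nominal 0.001 over 1000+ null regions.

## Chromatin marks and expression

Coverage tracks are normalized jointly to the geometric mean of their
genome-wide totals, which equalizes scaled totals while conserving the
log-sum; all downstream quantities are ratios, which makes them invariant
to rescaling any single track. Promoter marks (H3K27ac, H3K9ac, H3K4me3)
are quantified over TSS ± 1 kb, the others (H3K4me1, H3K36me3, H3K9me3,
H3K27me3) over TSS–TES; explicit region mode serves LMR windows and 5hmC
(treated as generic coverage). Condition ratios use a pseudocount of 1%
of the mark's mean per-kb genome-wide signal, scaled by target length, to
bound ratios at empty regions. Mark combinations average the log2 ratios
(a geometric mean of ratios). For the expression comparison, differential
genes are ranked by log2 fold-change; each mark's ratio is fit by a cubic
polynomial of rank ("non-linear regression" is otherwise unspecified, and
a cubic is the simplest monotone-trend-capable closed form), and the
combined model regresses rank on two marks' ratios with quadratic terms.
Under the generator's linear-Gaussian coupling with strength rho, the
per-mark R² concentrates near rho² and the two-mark combined R² near
2·rho²/(1+rho²), which the test suite checks at rho = 0.7.

## SNP enrichment

Trait SNP sets (leads plus precomputed R² > 0.8 proxies, duplicates
removed) are intersected with LMRs using the half-open convention
(`start <= pos < end`). The null is built from 100 (configurable) random
region sets, each with the identical length multiset as the LMR set,
placed uniformly (chromosome chosen proportional to length among those
long enough, optional exclusion mask honored by bounded rejection
sampling). Fold enrichment is observed over mean-null; significance is a
Pearson chi-squared (1 df, no continuity correction) on the 2×2 table of
in/out counts, observed versus pooled-null scaled to the observed total.
Because the expected row is an average over many draws but enters the
table as a same-size sample, this chi-squared is conservative; an
empirical permutation p-value over the null draws is always reported
alongside, and is the only p-value when no null draw captures a SNP.

## The synthetic-data generator

The generator emulates exactly the features the pipeline's statistics
depend on, not sequence-level reality:

* **Layout**: one toy chromosome (default 5 Mb), geometric inter-CpG
  spacing with mean 100 bp (~50,000 CpGs), and planted non-overlapping
  segments: 8 PMR blocks of 250 kb (40% of the sequence), 120 LMRs of
  800 bp, 10 UMRs of 4 kb, 6 of which host a 600 bp CpG island with
  5-fold CpG densification. LMR+UMR cover ~3% of the chromosome, the
  order of magnitude reported for somatic methylomes; PMR share, segment
  counts and lengths are all configurable. Islands coincide with their
  host UMR in the methylation layer but carry their own emission model.
* **Methylation**: per-CpG latent levels drawn per class — FMR
  Beta(17, 3), UMR Beta(2, 38), LMR Beta(6, 14), CGI Beta(1, 49), PMR
  Uniform(0, 1) — then coverage from a zero-truncated Poisson (mean 30)
  and methylated counts from a binomial. Replicate groups redraw each
  replicate's level from a Beta centered on the latent mean
  (concentration 50), giving the beta-binomial overdispersion a
  replicate-aware test must face; planted DMRs shift group B's latent
  levels with clipping to [0, 1].
* **Marks**: per-gene log2 ratios `rho·z + sqrt(1-rho²)·noise` around the
  standardized expression change, rendered as flat bedGraph coverage over
  each gene's quantification target.
* **SNPs**: each SNP falls inside an LMR with probability `fold × (LMR
  fraction)`, uniformly otherwise, so the expected fold over random
  placement equals the request.

Truth intervals for recovery metrics are the CpG-dyad spans of the
planted segments (first to last planted CpG + 2), matching how the
segmentation defines region ends; methylation regions are defined on
CpGs, not on the CpG-free sequence between them. All generators are
bit-reproducible given their seed, and scope their RNG so the caller's
random state is untouched.

What the generator does *not* emulate — and what passing tests therefore
do not show about real data: read-level artifacts (mapping bias,
incomplete bisulfite conversion), spatially correlated methylation noise
within a class, CpG-density–methylation coupling outside islands,
chromosome-scale heterogeneity, LD structure among SNPs, and realistic
peak-shaped mark coverage.

## Problem sizes and runtimes in the test suite

The suite exercises the full stack at sizes chosen to make every
stochastic bound statistically meaningful: segmentation recovery and
shuffle-FDR on the default ~50,000-CpG layout (20 seeds for recovery);
brute-force equivalence of region detection on chromosomes up to 500
CpGs; DMR type-I error on 1050 null regions and power at a planted 30%
difference for coverages 10/20/40; enrichment calibration over 200 seeded
null runs of 300 SNPs against 150 LMRs with 100 null sets each, and a
planted 3-fold set of 500 SNPs against 350 LMRs (~7% of the toy genome,
where the [2.5, 3.5] acceptance band spans about two standard errors of
the fold estimate). The complete suite runs in roughly ten minutes on a
single CPU.

## Known limitations

* The two-state HMM assigns each disorder-window score independent
  evidential weight although neighboring windows share 100 of 101 CpGs;
  transition probabilities absorb some of this, but domain boundaries are
  still only window-resolution estimates, and planted LMRs within a few
  kb of a PMR boundary are occasionally swallowed by the mask.
* The 4-column percent dialect carries no coverage, so such input gets
  unit pseudo-coverage and cannot drive coverage-dependent filters;
  count-based dialects are preferred.
* The rank-sum DMR p-value pools CpGs within a region and is therefore
  calibrated under exchangeable replicate noise, not under strong
  within-region spatial correlation.
* De-novo DMR discovery (binary segmentation) is out of scope; the
  differential module tests predefined regions only.
* LD computation, GWAS-catalog retrieval and ontology enrichment are
  inputs or out of scope, not recomputed.
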