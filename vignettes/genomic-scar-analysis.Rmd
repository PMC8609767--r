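---
title: "Genomic scar analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic scar analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gscar)
```

## The problem

Tumors with a deficient homologous recombination repair (HRR) pathway
accumulate large chromosomal gains and losses — "genomic scars". Three
established scar counters quantify this damage from an allele-specific
copy-number profile: loss of heterozygosity (LOH), telomeric allelic
imbalance (TAI) and large-scale state transitions (LST). Because raw scar
counts also rise with aneuploidy that has nothing to do with repair
deficiency, the combined score deducts ploidy:

$$\mathrm{HRD} = \mathrm{LOH} + \mathrm{TAI} + \mathrm{LST} - K \cdot \mathrm{Ploidy},$$

with \(K = 15.5\) and a positivity threshold of 30 by default. Both are
calibration constants of the assay this package models; they depend on
cancer type, sample type and platform and are exposed as plain parameters
(`scars$k`, `scars$threshold`), not re-derived here.

The input is a per-bin track of two signals from targeted SNP-panel
sequencing of a tumor against a normal control: the B allele frequency
(BAF; 0.5 at balanced heterozygous loci) and the log R ratio (LRR; log2
tumor/normal depth, 0 at copy-neutral loci).

## The admixture model

A tumor sample is a mixture of a tumor fraction \(p\) (purity) and
diploid, everywhere-heterozygous normal cells. For a genomic region where
the tumor carries \(n_A\) copies of one allele and \(n_B\) of the other
(total \(CN = n_A + n_B\)), the measured quantities are

$$\mathrm{BAF}^* = \frac{1 - p + p\,n_B}{p\,CN + 2(1 - p)},
\qquad
CN^* \cdot s = p\,CN + 2(1 - p),$$

where \(CN^* = 2^{\mathrm{LRR}} \cdot 2\) and \(s\) is a multiplicative
scale factor absorbing the normalization of sequencing depth (a sample
whose average ploidy differs from 2 has its LRR re-centered by
normalization; \(s\) undoes that). Solving the BAF equation for \(p\)
given a hypothesised genotype is `purity_from_cluster()`; the forward map
is `expected_baf()`. The two are exact inverses, which the test suite
checks to 1e-10 over the full genotype grid.

Assumptions worth stating: one dominant tumor clone (no subclonal copy
number), normal cells diploid at every locus, and BAF/LRR noise
independent across bins. Regions violating the single-clone assumption
will show intermediate BAF/CN values that fit no integer genotype.

## Preprocessing

* **Homozygosity filter.** Bins with BAF ≥ 0.95 or ≤ 0.05 are germline
  homozygous (or fully censored by LOH at high purity) and carry no
  allelic information; they are dropped from the BAF track only. Bounds
  are inclusive and configurable.
* **Mirroring.** Remaining BAF is folded to
  \(|\mathrm{BAF} - 0.5| + 0.5\), removing the arbitrary allele phase.
* **LRR density filter.** An optional outlier filter drops bins whose
  Gaussian-KDE density (Silverman bandwidth) falls below the 30th
  percentile of per-bin densities. It ships **disabled**: applied
  genome-wide as defined, it removes entire minority copy-number modes
  whenever the aberrant genome fraction is below the quantile — exactly
  the bins that carry the signal. It is appropriate (and tested) for
  tracks with gross scattered outliers; enable it via
  `lrr_outlier_filter$enabled`.

## Tree-recursion segmentation

Each chromosome arm is segmented separately for BAF and for LRR. At every
node the cumulative deviation from the mean,
\(S_k = \sum_{i \le k} (x_i - \bar{x})\), proposes its argmax and argmin
as candidate breakpoints; a candidate is accepted only if both children
have ≥ `min_bins` (10) bins, span ≥ `min_length_bp` (1 Mb), and differ in
mean at Welch-test level `alpha` (0.01). Of the two candidates the one
with the larger between-segment mean difference is tried first; recursion
proceeds depth-first into children, then across siblings. On noiseless
piecewise-constant input the recovered breakpoints provably coincide with
exhaustive SSE minimization, which the tests verify with an independent
dynamic-programming oracle on signals up to 600 bins and 3 breakpoints.

Adjacent segments whose value distributions overlap are then re-merged:
the overlap coefficient of the two segments' Gaussian KDEs (common
bandwidth, floored at 1e-3 so constant segments are handled exactly) is
computed for every adjacent pair, and the most similar pair is combined
while the overlap is ≥ `merge$kde_overlap` (0.5). The union of the BAF
and LRR breakpoint sets is then re-evaluated on both tracks, and segments
with fewer than `min_bins` bins or shorter than 1 Mb are iteratively
dissolved into the neighbor with the closer BAF mean. Finally, the last
p-arm and first q-arm segments are merged across the centromere gap when
both their BAF and LRR distributions pass the same overlap test.

Two consequences of the union/dissolution step matter downstream. First,
a dissolved sliver contributes its bins to the absorbing neighbor, so the
neighbor's mean is a mixture; ground-truth recovery is exact only when
every constant-genotype run has at least `min_bins` bins on its arm.
Second, when the homozygosity filter has censored most of a segment's
BAF bins (LOH at high purity), the surviving bins are unrepresentative;
a segment reporting BAF from fewer than max(3, 20%) of its bins has its
BAF set to missing, and the fraction is carried as `baf_frac`.

## Genotype clustering and the purity/ploidy fit

Segments of one genotype share \((\mathrm{BAF}^*, CN^*)\) regardless of
chromosome. Both quantities are converted to fractional percentile ranks
(ties averaged) and clustered with DBSCAN (`eps` 0.10, `minPts` 3 in rank
space); noise points become singleton clusters. Rank space equalizes the
two axes' scales but also scrambles near-tied values, so `eps` = 0.05
fragments everything when segment counts are modest; 0.10 chains
same-genotype groups while the second axis still separates genotypes.
Cluster summaries are genome-length-weighted **medians**: DBSCAN
occasionally chains one background segment into an event cluster, and a
median ignores it where a mean would bias Eq.-(4) purity by up to ~0.1 at
low purity.

The fit searches scale factors 0.5–2.5 in steps of 0.01. Per scale
factor, each imbalanced cluster's candidate genotypes
(\(n_A < n_B\), \(CN \le 8\)) each imply a purity; the candidate whose
implied purity reproduces the measured \(CN^*\) is preferred, but since
genotypes of different total CN predict nearly identical \(CN^*\) for the
same BAF, the choice among near-minimal-residual candidates is refined
toward the weighted-median purity consensus (two refinement passes).
Balanced clusters take the balanced genotype most consistent with the
consensus; BAF-censored clusters (mirrored BAF > 0.92 or
`baf_frac` < 0.7) may take any genotype and never contribute to purity.
The objective per scale factor is

dispersion (weighted MAD of per-cluster purities)
  + 0.5 × weighted mean CN residual
  + 0.01 × mean assigned copy number.

The first term is the spec of consistency; the second identifies the
scale factor when few imbalanced clusters exist; the third resolves the
whole-genome-doubling degeneracy — an assignment with every genotype
doubled at roughly half the purity reproduces BAF and \(CN^*\) exactly,
and the convention adopted (as in other allele-specific copy-number
callers) is the lower-ploidy reading. A genuinely doubled genome with any
odd-copy cluster is not affected, because its halved version has no
integer genotype.

Sample purity is the genome-length-weighted mean of per-cluster
estimates; fits with \(p < 0.20\) are flagged `low_confidence`, matching
the method's validated operating range. Integer copy numbers then invert
the model per segment, adjacent same-genotype segments are fused, and

$$\mathrm{Ploidy} = \sum_i \mathrm{Segs}_i\,CN_i +
  \Bigl(1 - \sum_i \mathrm{Segs}_i\Bigr) \cdot 2,$$

with \(\mathrm{Segs}_i\) the fraction of the annotated genome covered by
segment \(i\) and uncovered genome assumed diploid. (The printed form of
this formula elsewhere divides by a segment count \(n\), which is
dimensionally inconsistent with \(\mathrm{Segs}_i\) being genome
proportions; the proportion-weighted mean is the only reading that yields
ploidy 2 for a diploid genome.)

## Scar counters

All three counters run on integer allele-specific segments:

* **LOH**: maximal runs of segments with minor allele 0 and \(CN \ge 1\),
  longer than 15 Mb, excluding a run spanning the chromosome's whole
  covered extent (whole-chromosome LOH reflects ploidy, not scarring).
* **TAI**: segments with \(n_A \ne n_B\) that contain the outermost
  covered bin of an arm (targeted panels never reach the literal
  telomere), lie entirely within that arm, and exceed 11 Mb.
* **LST**: per arm, segments < 3 Mb are dropped, adjacent equal-genotype
  segments merged, and every breakpoint with both flanks ≥ 10 Mb counts.
  Segments crossing the centromere are split at the gap and no breakpoint
  is counted across it.

Length thresholds follow the printed wording (strict > 15 Mb and > 11 Mb;
LST flanks ≥ 10 Mb, filter < 3 Mb) and are configurable. Each counter is
tested against an independently written plain-loop rule evaluator on
randomized segment lists.

## Gene-level LOH from SNP variant fractions

The SNP-level caller classifies a site as informative when the control
variant fraction lies in [0.35, 0.65] (inclusive); an informative site is
an LOH site when the tumor fraction leaves that band (strictly), non-LOH
when it stays inside, and the gene verdict is a strict majority of LOH
over non-LOH sites (ties are no-LOH; no informative site is
"insufficient"). A caveat the rules imply: when the allelic loss is a
one-copy deletion, the retained-allele tumor VAF is
\((p + 2(1-p)c)/(2 - p)\), which for control VAF \(c \approx 0.5\) stays
inside the heterozygous band for purities between 0.40 and 0.50 — a
detection dead zone. Copy-neutral LOH (the typical mechanism for loss of
the wild-type copy) drifts as \((1-p)c + p\) and is detectable from
purity 0.4 upward; the property test simulates that mechanism.

## The simulator and what passing tests mean

`simulate_track()` draws the forward model directly: bins at a configured
density (default 1 per Mb, ~2,900 bins genome-wide) on GRCh37 chromosomes
1–22 and X skipping centromeres; per bin a fair coin picks the allele
phase, expected BAF/LRR follow the admixture equations, and independent
Gaussian noise is added (defaults: BAF sd 0.02, LRR sd 0.1 — magnitudes
typical of well-behaved panel data after depth normalization). The
default ground-truth profile places the common event classes (single-copy
gains, hemizygous deletions, balanced double gains, copy-neutral LOH) as
arm-level events recurring on several chromosomes, with true ploidy
≈ 2.12. Several events deliberately start a few bins after an arm
boundary, leaving flanks below the segmentation's minimum support — the
realistic case in which dissolution produces small, documented biases
rather than exact recovery.

What the simulator does **not** emulate: wave/GC artefacts in LRR,
depth-dependent (binomial) BAF noise, correlated noise along the genome,
subclonal events, and germline copy-number variants. Passing the
simulation-based tests therefore demonstrates correctness of the
inference given the model, not robustness to real-data artefacts.

Validation problem sizes were chosen to keep the whole suite in tens of
seconds: 2,900-bin genomes for pipeline runs, a 9-point dilution series,
600-bin signals for the segmentation oracle, 1,000 randomized lists for
the scar oracle, 500 replicates for the gene-LOH property.

## Numerical choices and degenerate inputs

* Welch tests guard zero variances: constant-vs-constant splits compare
  means exactly, so noiseless input is segmented exactly.
* KDE bandwidths are floored at 1e-3 (constant segments would otherwise
  have undefined bandwidths); overlap of identical constants is 1,
  of well-separated constants 0.
* Residual comparisons in the fit are rounded to 9 decimals before
  ordering so that exact ties resolve to the smaller copy number rather
  than by floating-point dust.
* A track with fewer than 10 LRR values skips the density filter with a
  warning; a chromosome with no covered arm yields no segments; a sample
  with no imbalanced cluster returns an undefined purity with
  `low_confidence = TRUE` and diploid-rounded copy numbers, so the report
  always carries the six headline fields.

## Known limitations

* Copy-neutral LOH at purity above ~0.9 is invisible: its LRR is 0 and
  its BAF is removed by the homozygosity filter. The affected segments
  default to a balanced genotype of the same total CN, so ploidy and the
  HRD deduction are unaffected, but the LOH counter undercounts at
  near-complete purity.
* Purity below 0.2 is outside the validated operating range; estimates
  are emitted but flagged.
* The fixed genotype grid (\(CN \le 8\)) truncates extreme amplifications;
  such clusters fit the nearest grid genotype.
* Scar thresholds and \(K\) are platform calibration constants; applying
  them to data from a very different bin density or noise regime without
  recalibration is not meaningful.
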