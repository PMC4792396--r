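---
title: "Estimating mitochondrial DNA copy number: models, QC rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating mitochondrial DNA copy number}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocn)
```

## The problem

Human cells carry hundreds to thousands of copies of the mitochondrial
genome, and the copy number per diploid cell (mtCN) varies strongly between
tissues — on the order of a few hundred in blood, a few thousand in skeletal
muscle, several thousand in liver — and between individuals of the same
tissue. mtCN is also where mitochondrial genetics meets ageing: heteroplasmic
variants in the control region, which regulates mtDNA replication, accumulate
with age in specific tissues, and their minor allele frequency (MAF) can be
associated with shifts in copy number. `mitocn` implements the quantitative
machinery for this kind of study: mtCN estimation from whole-genome
sequencing coverage and from droplet digital PCR (ddPCR), the quality-control
rules that make coverage-based estimates trustworthy, a misalignment-risk
model for nuclear insertions of mtDNA (NUMTs), and the downstream statistical
battery (age, sex, haplogroup, heteroplasmy burden, site-specific MAF).

## The coverage estimator

A sequencing run samples fragments roughly uniformly from all the DNA in the
library. If each diploid cell contributes two copies of every autosome and
`mtCN` copies of the mitochondrial genome, the expected ratio of
mitochondrial to autosomal *coverage* (aligned bases per mappable reference
base) is `mtCN / 2`. The estimator is therefore

$$\widehat{mtCN} = 2\,\frac{C_{mt}}{\tfrac1{K}\sum_{k=1}^{K} C_k},$$

with $C_{mt}$ the mitochondrial coverage and the denominator the mean
coverage over the $K$ retained autosomes. Three details matter in practice:

* **Mappable bases.** Reference assemblies contain long runs of `N`s
  (centromeres, gaps) that can never receive alignments. Per contig, runs of
  **more than 5 consecutive Ns** are masked and coverage is computed against
  the remaining (mappable) bases. A run of exactly 5 is kept — the threshold
  is strict (`build_reference_index()`).
* **Fragments, not reads.** Each properly paired fragment contributes its
  *insert size* — the outer-mate-to-outer-mate span, which equals the merged
  read length when mates overlap — exactly once to its contig
  (`tally_fragments()`). Pairs mapping to different contigs are discarded,
  and a mate-distance filter keeps only pairs within 3 SD of the insert-size
  distribution. Because nothing in the input says what the SD is before
  filtering, the filter is two-pass: the distribution is estimated from all
  same-contig pairs, then the cut is applied. The filter is centred on the
  mean (|insert − mean| ≤ 3 SD), the natural reading when the distribution
  is roughly symmetric; measuring from zero would make the lower cut
  vacuous.
* **No mapping-quality filter, duplicates kept.** Defaults follow the
  lenient alignment protocol this estimator was designed for: filtering by
  mapping quality would bias the mitochondrial contig (where NUMT-like reads
  have lowered MAPQ) differently from the autosomes.

The estimator cancels depth exactly — multiplying all aligned bases by a
constant leaves it unchanged — so its error is dominated by fragment-count
noise on the least-covered side, usually the autosomes at low depth or the
mitochondrial contig at low mtCN.

## Quality control

Two sample-level rules (`filter_samples()`), applied independently with the
first taking precedence as the recorded reason:

1. **LOW_MT_BASES** — mitochondrial aligned bases ≤ 60% of the mitochondrial
   genome length. Such a sample cannot support a stable mitochondrial
   coverage estimate.
2. **HIGH_AUTOSOMAL_SD** — within its tissue, the sample's
   $\log_{10}(\mathrm{SD}/\mathrm{mean})$ of autosomal coverage is a Grubbs
   outlier. We read "logarithmic normalized SD" as log10 of the coefficient
   of variation; the alternative reading (log SD divided by mean) mixes
   units and was rejected. Only the high side excludes: a sample with
   unusually *uniform* coverage is not defective. The Grubbs step is applied
   once per tissue (single pass), mirroring a one-shot cohort cleaning; it
   is deliberately not iterated, so at most one sample per tissue can fall
   to this rule in a run.

Chromosome-level rule (`select_excluded_chromosomes()`): per tissue, the SD
of each autosome's coverage across samples, normalized by the tissue's mean
autosomal coverage, goes into a Grubbs test; the flagged chromosome is
removed and the test repeated until no outlier remains. A chromosome flagged
in **at least half** of the tissues is dropped from the mtCN denominator
everywhere. Iteration is the default because two chromosomes can be inflated
simultaneously (in real data, chromosomes 16 and 19 — dense in segmental
duplications — are the usual casualties); a single-pass mode exists for
comparison. As with samples, only inflated variance flags a chromosome.

The Grubbs test itself (`grubbs_test()`) uses the exact two-sided critical
value $\frac{n-1}{\sqrt n}\sqrt{t^2/(n-2+t^2)}$ with $t$ the upper
$\alpha/(2n)$ t-quantile at $n-2$ df; the implementation reproduces the
published 5% table values (1.715, 2.290, 2.709, 3.128 at n = 5, 10, 20, 50).

## ddPCR estimation

ddPCR partitions a reaction into ~20,000 droplets and counts droplets
containing template; after the instrument's Poisson correction for
multi-template droplets ($\hat\lambda = -n\log(1-k/n)$,
`ddpcr_poisson_correct()`), the corrected counts are absolute molecule
numbers. With a single-copy nuclear reference locus (2 copies per diploid
cell),

$$\widehat{mtCN} = 2\,\frac{\text{mt counts}\times\text{mt dilution}}
                           {\text{n counts}\times\text{n dilution}},$$

averaged over replicates, with the replicate SD (and the SD normalized by
the sample mean) carried along (`mtcn_from_ddpcr()`). Dilution factors
matter for high-mtCN tissues, where the mitochondrial target must be
measured on far less template than the nuclear one in a separate reaction;
the factors restore a common scale. The units question — copies per
reaction vs copies per µl — is absorbed by the dilution contract as long as
one convention is used consistently within a dataset.

`reproducibility_summary()` reports both normalization conventions that
appear in multi-method comparisons (per-sample SD/mean averaged per tissue,
and mean SD divided by the tissue mean), labelled separately, because the
two differ when mtCN varies across samples.

## NUMT misalignment risk

Recent nuclear insertions of mtDNA are sequence-identical to the organelle
genome, so a fragment wholly contained in such a NUMT can be aligned to the
mitochondrial contig with no penalty, inflating mtCN. The model asks: what
is the probability that a uniformly placed nuclear fragment lies fully
inside some NUMT? For insert size $i$, a NUMT of length $j \ge i$ offers
$j-i+1$ such placements out of $l-i+1$ genome-wide ($l$ = mappable genome
length), so

$$p = \sum_i w_i\,\frac{\sum_{j\ge i}(j-i+1)}{l-i+1},$$

with $w_i$ the empirical insert-size frequencies
(`misalignment_probability()`). Overlapping catalogue intervals are merged
first so placements are never double-counted. Average autosomal coverage
does not belong inside a probability; it converts $p$ into an expected
per-run count of misattributed fragments, which is reported alongside. A
"printed" compatibility mode sums the unweighted ratio over all insert
sizes 1..M; it is retained for comparison but is not a probability (it can
exceed 1), which is why the weighted form is the default.

## The association battery

All mtCN values are log10-transformed per tissue before testing — copy
numbers are closer to log-normal than normal, and linear-model residuals
must be roughly normal for the F- and t-tests used here. Normality is
checked with a Shapiro-Wilk test (`prepare_tissue()`); while it rejects at
α = 0.05 and at most `max_exclusions = 2` samples have been removed, the
sample with the largest |z| of log10 mtCN is excluded and the test repeated.
This is the gate that removes rare extreme-mtCN samples (tissue-specific
copy-number explosions of 20–100-fold have been observed in real cohorts);
the cap keeps the gate from trimming a genuinely skewed distribution into
shape silently — if normality is still rejected, analysis proceeds with a
warning flag. Note that at α = 0.05 the gate removes a sample from ~5% of
perfectly log-normal cohorts; that is the designed false-positive rate of
the check, not a bug.

On the prepared values: simple regression/Pearson correlation
(`correlate()`, with optional sex-stratum, age-window and mtCN-threshold
filters for subgroup re-analyses), one-way F-tests for sex and for each
major haplogroup (H, J, U) against the residual set (`group_compare()`),
Pearson correlation of log mtCN between all tissue pairs matched on
individual (`tissue_pair_matrix()`), partial regression for the joint
effect of age, site MAF and heteroplasmy count (`partial_regression()`,
reporting each predictor's partial t-test p, which for a single predictor
reduces exactly to the simple-regression p), and site-level MAF tests
(`site_maf_tests()`).

Multiple-testing correction is Benjamini-Hochberg, applied **within one
family per analysis type and method** (the convention of method-stratified
supplementary tables), not globally — `association_battery()` wires this
up. Site-MAF families are per arity (singles, pairs, triplets). For MAF
tests, only sites carried by ≥ 10 individuals are tested; non-carriers
enter at MAF 0, below the 2% detection floor, because tissue-wide
correlations include apparent non-carriers (a carriers-only mode exists).
For pairs/triplets the combined predictor is the **sum** of member-site
MAFs among individuals carrying all member sites — a combined-burden
reading; min and mean are selectable since the choice is genuinely open. Sex-stratified MAF tests are corrected within stratum.

## The synthetic cohort: what it emulates and what it does not

`simulate_cohort()` generates the study conditions the package is tested
under: 150 individuals, ages uniform on 0–96 years, ~56% male, three
tissues at scales 257 (BL), 2873 (SM) and 7023 (LIV) copies per diploid
cell with log10-normal spread 0.15; age slopes on log10 mtCN of −0.004/yr
(males) and −0.0015/yr (females) in SM, +0.002/yr in LIV, 0 in BL;
heteroplasmic sites 408 and 16327 (light-strand promoter and
termination-associated sequence, both SM-specific in real data) whose MAF
rises with age toward the observed ceilings of 28.2% and 20%, with a 2%
detection floor; and one extreme sample per 150 whose SM mtCN is multiplied
100-fold. The number of outliers is deterministic (`round(n × rate)`) rather
than Binomial so that the default cohort always contains exactly one — the
condition the recovery checks are defined against.

Two generator parameters are the package's own choices where the emulated
study reports none:

* **MAF noise** is normal on the logit scale (SD 0.5) around the
  age-dependent mean, which respects the (0, ceiling) bounds without
  truncation artifacts; the observed data constrain ranges, not
  distributions. A side effect is that carrier prevalence at the planted
  sites (~60–80%) is higher than in the real cohort (~30–45%); this affects
  power, not correctness, of the recovery checks.
* **MAF→mtCN coupling** is −1.5 log10 units per unit MAF at both sites: at
  the maximal observed MAF of ~0.28 this halves-to-thirds copy number, a
  magnitude consistent with a replication-regulatory variant being
  detectable but not catastrophic.

With these defaults the planted SM age correlation (direct slope plus the
age-borne MAF coupling) is around −0.7 — stronger than the r ≈ −0.25
reported in real muscle — because a 150-sample desk-scale cohort needs
effects detectable in ≥ 80% of seeds for the recovery properties to be
sharp. The `effects = "null"` configuration zeroes every slope, coupling
and outlier for type-I-error checks.

`simulate_fragments()` inverts the coverage estimator (expected
mitochondrial coverage = depth × mtCN/2, per-contig Poisson fragment
counts, truncated-normal insert sizes) and can emit proper SAM pairs
(`write_fragments_sam()`) to exercise the BAM path; it deliberately models
no sequencing errors, GC bias, or real alignment — recovery under this
generator shows the estimator and its plumbing are correct, not that real
reads are unbiased. `simulate_ddpcr()` models droplet partitioning
(Binomial positives under Poisson occupancy, instrument back-conversion)
with ~3% lognormal template-pipetting noise per replicate, shared between
targets in multiplexed reactions and independent in separate ones — which
is why separate-reaction replicate scatter is larger, matching the
qualitative pattern seen between the two ddPCR workflows.

## Numerical choices and degenerate inputs

* Log transform base: 10, fixed; r and p are base-invariant, coefficients
  are reported in log10 units per predictor unit.
* Grubbs with zero variance: no outlier, with a warning. Non-finite inputs
  (a sample with exactly zero autosomal dispersion would yield log(0))
  skip the Grubbs step rather than poison it.
* `tally_fragments()` on unpaired-only input warns and counts reads by
  length, flagging the table `single_end`; zero passing fragments is an
  error, not an empty table.
* ddPCR replicates with zero nuclear counts are dropped with a warning;
  a sample losing all replicates is an error. Reactions at > 99% positive
  droplets warn of saturation.
* Collinear predictors in `partial_regression()` are rejected naming the
  offending pair; constant predictors are rejected everywhere.
* 0-based half-open coordinates internally for intervals (BED-compatible);
  `GRanges` conversion happens at the boundary.

## Problem sizes used by the checks

The test suite and `scripts/acceptance.R` run the estimator-recovery grid
(true mtCN ∈ {100, 250, 2800, 7000} at 0.5× depth) on a toy genome of three
2-Mb autosomes plus a full-length (16,569 bp) mitochondrial contig. At this
size the binomial sampling floor of the estimator (~1.9% relative SD at
mtCN 100, dominated by ~2,800 mitochondrial fragments) sits comfortably
inside the 2% median-error band being checked, while a full run takes
seconds; scaling the autosomes further up only shrinks the denominator
noise. Cohort-level checks use 100 seeds of the default 150-individual
cohort; the ddPCR checks use 3-replicate runs across 100 seeds.

## Known limitations

* Capture-enriched data are processed identically to shotgun but labelled
  `capture`; enrichment saturation is not modelled, so capture estimates
  are relative, never absolute.
* The NUMT model treats the catalogue as exact and fragments as uniformly
  placed; it estimates a rate, it does not identify which reads are
  NUMT-derived.
* The battery's haplogroup comparison takes labels as given — haplogroup
  calling from sequence is out of scope, as is heteroplasmy calling
  (heteroplasmy tables are consumed as input).
* Partial regression quantifies conditional association, not causation.
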