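# mitocn

Estimation and analysis of mitochondrial DNA copy number (mtCN) — the
number of mitochondrial genome copies per diploid cell — from whole-genome
sequencing coverage and from droplet digital PCR (ddPCR), for multi-tissue,
multi-individual studies.

mtCN varies over an order of magnitude between tissues (hundreds in blood,
thousands in skeletal muscle and liver) and between individuals, changes
with age in a tissue- and sex-dependent way, and interacts with
heteroplasmy — the coexistence of mtDNA alleles within one individual,
quantified by the minor allele frequency (MAF) at control-region sites that
regulate mtDNA replication. This package is for researchers who want to
estimate mtCN reproducibly from standard inputs (FASTA reference, BAM/SAM
alignments or pre-tabulated coverage, ddPCR droplet counts) and run the
full association battery against cohort covariates.

## The core quantities

**Coverage estimator.** Per chromosome, coverage is aligned bases divided
by *mappable* bases (contig length minus poly-N runs > 5 bp). Each properly
paired fragment contributes its insert size once, after a two-pass
mate-distance filter (±3 SD of the insert-size distribution). Then

```
mtCN = 2 * C_mt / mean(C_autosomes)
```

with noisy samples and high-variance chromosomes removed beforehand by
Grubbs-test QC rules (samples: log10 of the autosomal coverage CV; ≤ 60%
mitochondrial representation; chromosomes: normalized per-tissue coverage
SD, excluded when flagged in ≥ 50% of tissues).

**ddPCR estimator.** With Poisson-corrected droplet counts of a
mitochondrial target and a single-copy nuclear target,

```
mtCN = 2 * (mt_counts * mt_dilution) / (n_counts * n_dilution)
```

averaged over replicates, with replicate SDs reported.

**NUMT misalignment risk.** The probability that a nuclear fragment lies
fully inside a catalogued NUMT (and could therefore be misattributed to the
mitochondrial genome): `p = Σ_i w_i · Σ_{j≥i}(j−i+1) / (l−i+1)` over the
empirical insert-size distribution, with an expected per-run misattributed
fragment count.

**Association battery.** Per tissue: log10 transform, Shapiro-Wilk
normality gate (removes rare extreme-mtCN samples), Pearson/linear
regression against age (with sex strata), sex and haplogroup F-tests,
inter-tissue correlation matrix, partial regression of age + site MAF +
heteroplasmy count, and site-level MAF tests (≥ 10 carriers; pairs/triplets
by MAF sum) — all Benjamini-Hochberg-corrected within analysis families.

A synthetic-data module (`sim_config()`, `simulate_reference()`,
`simulate_fragments()`, `simulate_ddpcr()`, `simulate_cohort()`) generates
every input with known ground truth and is the backbone of the test suite.

## Worked example

```r
library(mitocn)

cfg <- sim_config(seed = 42)                  # 150-individual, 3-tissue cohort
ref <- simulate_reference(cfg)                # FASTA + NUMT BED + index
fr  <- simulate_fragments(cfg, true_mtcn = 2873, index = ref$index)
tab <- tally_fragments(fr, ref$index, sample_id = "IND001", tissue = "SM")
mtcn_from_coverage(tab, ref$index)
#>   sample_id tissue  method mtcn chrom_norm_sd qc_pass
#> 1    IND001     SM shotgun 2826       0.01465    TRUE
```

The estimate (2826) recovers the simulated truth (2873) to ~1.6%; the
per-sample chromosomal SD (1.5% of mean autosomal coverage) is the
reproducibility figure a real shotgun run would report. The ddPCR path:

```r
dd <- simulate_ddpcr(cfg, true_mtcn = 260, replicates = 3, tissue = "BL")
mtcn_from_ddpcr(dd)
#>   sample_id tissue method  mtcn replicate_sd normalized_sd n_replicates qc_pass
#> 1        S1     BL  ddpcr 244.4        19.51       0.07983            3    TRUE
```

Cohort-level associations, with the planted effects recovered:

```r
sim <- simulate_cohort(cfg)
bat <- association_battery(sim$cohort, sim$heteroplasmy)
subset(bat$results, analysis %in% c("age", "maf"),
       select = c(test_id, tissue, r, p_adj, n))
#>      test_id tissue      r    p_adj   n
#> 1        age     BL  0.120 1.44e-01 150
#> 2        age    LIV  0.303 2.47e-04 150
#> 3        age     SM -0.685 1.62e-21 149
#> 19   maf_408     SM -0.653 3.81e-19 149
#> 20 maf_16327     SM -0.588 3.05e-15 149
```

Skeletal-muscle mtCN falls with age and with MAF at the two planted
control-region sites (408, 16327), liver mtCN rises with age, blood shows
nothing — exactly the structure the generator plants. The normality gate
catches the one injected 100-fold outlier before any of this runs:

```r
bat$exclusions
#>    individual_id tissue    reason statistic    shapiro_p
#> SM        IND067     SM NORMALITY  5.954405 7.914545e-08
```

And the NUMT risk for this toy reference (two planted NUMTs, 800 bp total):

```r
risk <- misalignment_probability(numt_catalog(ref$bed),
          insert_size_histogram(tab),
          mappable_l = sum(ref$index$mappable_bases[ref$index$autosome_names]))
risk
#> NUMT misalignment risk (empirical mode): p = 0.000335 (0.0335%)
#>   expected misattributed fragments: 28.14 of 84080
```

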