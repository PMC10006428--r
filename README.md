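# gymnotools

Statistical toolkit for the computational layer of giant gymnosperm genome
projects — written around the analyses of the *Torreya grandis* (Chinese
torreya) seed genome, whose 19-Gb assembly, ancient repeat landscape and
seed methylome typify the problems this package addresses. It is aimed at
genome-project analysts who need the recurring "bespoke" statistics of such
a study as tested, reusable functions rather than one-off scripts:

* **LTR retrotransposon dating** (`ltr_insertion_ages()`): the two LTRs of
  an intact element are identical at insertion; their divergence, corrected
  with the Kimura two-parameter distance
  *K* = −½·ln[(1 − 2*P* − *Q*)·√(1 − 2*Q*)], clocks the insertion time
  *T* = *K*/(2*r*) at the gymnosperm substitution rate
  *r* = 2.2×10⁻⁹ site⁻¹ yr⁻¹.
* **WGD detection from Ks** (`fit_ks_mixture()`, `density_summit()`): an
  EM-fitted Gaussian mixture over the paralog Ks distribution, with
  BIC-based component selection and summit location — the signature of an
  ancient whole-genome duplication is a mixture component/summit in the
  Ks ∈ 1–2 window.
* **WGBS statistics** (`estimate_conversion_rate()`,
  `call_methylated_sites()`, `binned_levels()`, `gene_metaprofile()`,
  `expression_ventile_gbm()`, `detect_dmv()`, `common_dmvs()`): lambda
  spike-in conversion rate; one-sided binomial site calling against the
  non-conversion null with per-context Benjamini–Hochberg FDR;
  count-pooled methylation levels in windows, gene metaprofiles and
  expression ventiles; demethylation-valley (DMV) discovery and
  cross-sample intersection; χ² enrichment.
* **HGT screening** (`screen_candidates()`): the average-bitscore (ABV)
  contrast over three BLAST database partitions (out-/mid-/in-group),
  with the "≤ 100 hits, one per species" reduction; candidates satisfy
  ABV(out) > ABV(mid).
* **Assembly QC arithmetic** (`contig_n50()`, `coverage_fold()`,
  `qv_to_accuracy()`, `genome_size_from_kmer_histogram()`,
  `telomere_scan()`, `centromere_monomer_summary()`).
* **Seeded simulators** (`simulate_ltr_pairs()`, `simulate_ks()`,
  `simulate_methylome()`, `simulate_hgt_tables()`,
  `simulate_feature_genome()`): generate every input the pipeline consumes
  together with ground-truth tables, so each stage is testable without any
  external download.

Readers/writers cover FASTA, GFF3, Bismark-style CX reports, BLAST
outfmt-6 (+ species map) and BED.

## Worked example

Date a burst of LTR insertions, locate a planted WGD summit, and call a
demethylation valley — all from simulated inputs with known truth:

```r
library(gymnotools)

## LTR dating: 50 elements inserted 10 Myr ago
sim  <- simulate_ltr_pairs(n_elements = 50, ltr_length = 2000,
                           true_age = 1e7, seed = 42)
ages <- ltr_insertion_ages(sim$pairs)
head(ages[, c("element_id", "P", "Q", "K", "T")], 3)
#>   element_id     P      Q      K        T
#> 1    ltr0001 0.029 0.0160 0.0466 10584391
#> 2    ltr0002 0.031 0.0175 0.0503 11437712
#> 3    ltr0003 0.031 0.0115 0.0440  9997221
mean(ages$T) / 1e6
#> [1] 9.91          # Myr; truth is 10

## Ks mixture: recent duplicates at 0.3 + ancient WGD at 1.4
fit <- fit_ks_mixture(simulate_ks(n_pairs = 2000, seed = 42),
                      n_components = 2, seed = 1)
fit$means
#> [1] 0.303 1.397
density_summit(fit, search_range = c(1, 2))
#> [1] 1.4

## Methylome: conversion rate, site calls, and a planted 10-kb valley
meth <- simulate_methylome(seed = 42,
                           dmvs = data.frame(start = 80001, end = 90000))
estimate_conversion_rate(meth$lambda_records)
#> bisulfite conversion rate: 0.9954 (40133 / 40317 reads)
detect_dmv(meth$records)
#> GRanges object with 1 range and 4 metadata columns:
#>       seqnames      ranges strand |   n_sites   level_cg  level_chg  level_chh
#>   [1]     chr1 80039-89863      * |       364 0.00774818 0.00635471 0.00912721
```

The per-element table gives the transition (`P`) and transversion (`Q`)
proportions, the corrected distance `K` and the age `T` in years; the DMV
call recovers the planted valley to within one inter-site spacing, with
pooled levels below 1% in all three contexts.

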