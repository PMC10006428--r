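---
title: "Methods behind gymnotools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind gymnotools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gymnotools)
```

gymnotools implements the statistical layer that recurs in large gymnosperm
genome projects: dating LTR retrotransposons, locating whole-genome
duplication (WGD) signatures in Ks distributions, whole-genome bisulfite
sequencing (WGBS) statistics, an average-bitscore screen for horizontal gene
transfer (HGT), and the arithmetic of assembly reports. This vignette
explains each model, its assumptions, the tunable parameters, and the design
choices made where several constructions were defensible.

## Coordinate convention

All genomic intervals are carried as `GRanges`/`IRanges` objects, i.e.
1-based closed coordinates, the Bioconductor convention shared by every
interval operation the package delegates to (`reduce`, `intersect`,
`overlapsAny`). Conversion to 0-based half-open coordinates happens at
exactly one place, the BED boundary (`write_bed()`/`read_bed()`), and GFF3
input needs no conversion at all. Concentrating the conversion at one
boundary keeps it testable as an involution (export then import restores
the integers).

## LTR retrotransposon dating

At insertion, the two long terminal repeats of an intact element are
identical; they then diverge neutrally. The package aligns each 5'/3' LTR
pair globally (linear gap scoring, default match 1 / mismatch −1 / gap −2),
counts transitions and transversions over columns where both rows carry a
base (pairwise deletion of gap and ambiguity columns), and corrects for
multiple hits with the Kimura two-parameter distance

$$K = -\tfrac{1}{2}\,\ln\!\big[(1 - 2P - Q)\sqrt{1 - 2Q}\big],$$

where $P$ and $Q$ are the transition and transversion proportions. The
insertion time is $T = K / (2r)$ — the factor 2 because divergence
accumulates along both branches — with $r = 2.2\times10^{-9}$
substitutions/site/year, the rate conventionally applied to gymnosperms.
$r$ is configurable per run.

Numerical choices: inputs where the correction is undefined
($1-2P-Q \le 0$ or $1-2Q \le 0$) raise a typed condition
(`k2p_saturation_error`); `ltr_insertion_ages()` converts these to
`T = NA`, flags the element, and reports the saturated count, rather than
clamping to an arbitrary large age. Whether to compute K on full or trimmed
alignments is not standardized; the package uses the full pairwise
alignment with pairwise deletion.

The simulator (`simulate_ltr_pairs()`) copies a random ancestral LTR twice
and applies a Poisson number of substitution events per site per copy
(expectation $rT$), each event a transition with probability 2/3. Multiple
hits therefore occur, so the K2P correction is genuinely exercised: a
proportion-only simulator would make the correction untestable. Recovery
tests use 200 elements with 2-kb LTRs at true ages of 1, 10 and 25 Myr and
require the mean estimated age within 10% of truth.

## Ks mixtures and WGD detection

A WGD leaves a coherent burst in the distribution of synonymous distances
(Ks) among paralog pairs. `fit_ks_mixture()` fits a Gaussian mixture by EM,
written in-package because the fit itself is the analysis (an independent
EM implementation, mclust, cross-checks it in the test suite). Details:

* Fitting is on the raw Ks scale, truncated to (0.05, 5): the lower cutoff
  excludes allelic and very recent duplicates, the upper bound matches the
  plotted range; the reported summit statements in this literature are
  raw-scale. Truncation discards out-of-range values rather than using a
  truncated likelihood — simpler, and adequate for summit location.
* Ten restarts seeded from data quantiles with jitter; best fit by
  log-likelihood; E-step in log space; component standard deviations
  floored at $10^{-4}$; convergence at a log-likelihood change below
  $10^{-8}$.
* The log-likelihood is asserted non-decreasing at every iteration; a
  decrease aborts the fit rather than returning a silently broken model.
* `select_components()` chooses k by BIC ($-2\ell + (3k-1)\log n$), ties
  toward smaller k.
* `density_summit()` reports the grid argmax (default step 0.01) of the
  fitted density over a search range, warning when the summit pins to a
  boundary. The default simulator plants components at Ks 0.3 and 1.4 with
  standard deviations 0.1 and 0.25 — a recent-duplicate background plus an
  ancient-WGD peak inside the 1–2 window — and recovery tests require both
  means and the summit within 0.05.

## Bisulfite methylome statistics

**Conversion rate.** The unmethylated lambda-phage spike-in estimates the
bisulfite conversion rate as pooled converted reads over total reads at
lambda cytosines. Its complement, the non-conversion rate, is the null
success probability of the site caller. The spike-in size is a parameter
(the ratio is library-dependent); simulations default to a 99.5% conversion
rate.

**Site calling.** Each cytosine with coverage at least `min_coverage`
(default 4; no coverage floor is standardized, but below 4 reads the test
is vacuous) gets a one-sided upper-tail binomial p-value for its methylated
count under the non-conversion null. The upper tail is the only direction
under which "methylated" is the alternative hypothesis. FDR control is
Benjamini–Hochberg *within each context class* (CG, CHG, CHH), because the
three contexts carry very different null burdens; a site is called at
q < 0.05.

**Levels.** All levels are count-pooled — $\sum mC / \sum (mC + umC)$ —
never means of per-site ratios; the two differ whenever coverage varies
(the suite pins this with a two-site example: 10/10 and 0/90 pool to 0.10,
not 0.50). Window levels use 10-kb bins by default, the last partial bin
retained, and empty bins report `NA`, not zero. CG sites are kept
per-strand; symmetric-CG collapsing is not performed.

**Gene profiles.** `gene_metaprofile()` pools counts into strand-aware
bins: fixed-width flanks (default 2 kb) and exonic/intronic coordinates
each scaled into `n_bins` bins, with upstream meaning 5' of the gene. A
minus-strand gene therefore produces exactly the mirror of its plus-strand
equivalent, which the suite asserts. `expression_ventile_gbm()` ranks genes
by TPM with stable ties by gene id, cuts them into 20 equal groups, and
reports median TPM plus pooled exonic level per context per group.

**Demethylation valleys.** A DMV is an extended region where methylation is
low in every cytosine context. A covered site qualifies when its per-site
level is below the threshold (default 5%). Qualifying sites are clustered
*within each context* (gap at most `max_gap`, default 2 kb), and the
contexts' low intervals are intersected (`mode = "all"`, default) or
unioned (`mode = "any"`; both readings of "low in any context" circulate,
and the flag exposes both). Candidates must span `min_length` (default
1 kb), contain `min_sites` covered cytosines (default 10), and pass a
pooled per-context re-check below the threshold. The per-context clustering
is the load-bearing choice: at depth 20 a truly demethylated site shows a
sampled level of exactly 1/20 = 5% about 13% of the time, so any rule in
which one such site breaks a run fragments every real valley; and a
context-blind clustering chains through background CHH (genuinely ~4%
methylated almost everywhere) until the merged region fails the CG check.
Intersecting per-context intervals is robust to both failure modes, and
recovery tests require a per-region Jaccard of at least 0.9 against
planted valleys. `common_dmvs()` intersects sample DMV sets at base-pair
resolution for the cross-sample "common DMV" operation, and
`enrichment_chi2()` is the uncorrected Pearson test on a 2×2 table (e.g.
transcription factors in/out of DMVs).

## HGT screening by average bitscore

Query proteins are searched against three database partitions — out-group
(prokaryotes and fungi), mid-group (non-gymnosperm plants), in-group
(gymnosperms) — with an e-value cutoff of $10^{-5}$. Per query and
database, hits reduce to one best hit per species (bitscore, then e-value,
then subject id — a total order, so the screen is invariant to input row
order), capped at the 100 best; the mean of kept bitscores is the ABV. A
query is a candidate when its out-group ABV exists, rests on at least
`min_out_hits` hits (default 5; single-hit ABVs are noise-dominated), and
exceeds its mid-group ABV. A missing mid-group passes vacuously but is
flagged `mid_absent`, since that signature is as consistent with
contamination as with transfer. Candidates are screening output only; the
confirmatory phylogenetic inspection is an external follow-up by design.

## Assembly QC arithmetic

N50 is the largest length L such that contigs at least L long sum to half
the assembly (ties resolve to the largest qualifying length). Coverage
folds, anchoring rate and repeat fraction are plain ratios rounded half-up
(not banker's rounding) to one decimal, the convention under which report
values such as 96.5× or 99.1% are recovered from their raw inputs; QV
converts to accuracy as $(1 - 10^{-QV/10}) \times 100$. The k-mer genome
size is total k-mer observations above a low-depth error cutoff divided by
the homozygous-peak depth, with the cutoff defaulting to the histogram's
first local minimum. Telomere scanning counts non-overlapping TTTAGGG
copies in the 3' terminal window and its reverse complement in the 5'
window (window 10 kb, 10 copies to flag — detection parameters are not
standardized in reports, so both are configurable), and
`centromere_monomer_summary()` aggregates tandem-repeat annotations by
period to identify the dominant (e.g. 101-bp) centromeric monomer.

## What the simulators do and do not emulate

The generators produce every input the pipeline consumes, with ground-truth
tables, under a single seeded RNG (same seed, byte-identical output). They
emulate: LTR divergence with multiple hits and transition bias;
per-cytosine binomial sampling with Poisson coverage, context-specific
levels (defaults 83%/69%/4% for CG/CHG/CHH), planted near-zero valleys and
a lambda spike-in; three-database bitscore structure with planted
transfers; Gaussian Ks mixtures truncated at zero; and chromosomes with
planted telomere/centromere arrays. They do not emulate read-level error,
bisulfite alignment artifacts, indels in LTRs, mapping bias, copy-number
variation in repeats, or spatial autocorrelation of methylation beyond the
planted valleys — so passing recovery tests demonstrates correctness of
the statistics under their own sampling assumptions, not robustness to
upstream artifacts in real libraries.

## Problem sizes and determinism

The test suite and the acceptance script run the recovery analyses at
moderated scales chosen to exercise the asymptotics without waste: 200
elements × 2-kb LTRs per age point, 2000 Ks pairs, $10^5$ cytosines for
caller calibration, 8000 sites over 200 kb for valley recovery, and 100
queries × 220 species for the screen. All randomness flows through
explicit seeds; the acceptance script derives per-stage sub-seeds from its
`--seed` argument.

## Known limitations

* The EM uses unconstrained component variances; heavily overlapping
  components at small n can end in a non-converged (flagged) fit.
* Truncation by discarding biases mixture weights near the fit-range edges;
  summit location is insensitive to this, but weights should not be
  over-interpreted.
* The DMV caller reports bounds at the outermost qualifying sites, so
  resolution is one inter-site spacing; sparse contexts widen this.
* The metaprofile bins by physical position within segments; it does not
  model intra-read correlation, and genes shorter than a bin contribute
  coarsely.
* `read_gff_genes()` handles gene/mRNA/exon (or exon-on-gene) GFF3 and
  ID/Parent attributes only, by design.
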