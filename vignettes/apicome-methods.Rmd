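---
title: "Methods: reconstructing the apicome from paired LCM profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reconstructing the apicome from paired LCM profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apicome)
```

## The measurement design

Laser-capture microdissection cuts the apical (lumen-facing) and basal
(stroma-facing) halves of the intestinal epithelial monolayer separately, at
two zones along the villus axis (tip and base), in each subject. The
resulting design is paired twice over: four RNA-seq samples per subject
(2 compartments x 2 zones), and a matched iBAQ proteome for a subset of
subjects. Two physical facts shape the statistics:

* the basal compartment is much thinner than the apical one (mean widths of
  roughly 15 vs 7 micrometers), so basal samples yield systematically fewer
  UMIs — every comparison must be made on per-sample relative abundances,
  never yields;
* cohorts are small (5–8 subjects), so large-sample approximations to rank
  test null distributions are not trustworthy and all tests here are exact.

## Normalization and the pseudo-number

`total_count_normalize()` divides each sample by its UMI sum, making columns
sum to 1. Ratios of relative abundances are then depth-free: multiplying all
of a subject's raw counts by any factor leaves every score unchanged (this
invariance is asserted in the test suite across 100 seeded simulations).

Log-ratios need protection at zero. The pseudo-number `pn` is defined as the
smallest *nonzero* normalized expression across all samples and genes of the
data set (`compute_pseudo_number()`), computed once per species over the
combined matrix. Adding `pn` to numerator and denominator bounds a ratio
with a zero denominator at roughly `log2((x + pn)/pn)` while leaving
well-measured ratios essentially untouched, since `pn` is orders of
magnitude below typical expression. The proteomics ratio uses a fixed
`pn = 1e-6` on column-normalized iBAQ, matching the scale of its smallest
reliable abundances.

## The polarization fit

For each gene above the testing floor (mean normalized expression `> 1e-5`;
genes below it are too close to the sampling noise floor for an 8-subject
rank test to be meaningful), `polarization_test()`:

1. averages the two zones within each compartment and subject, giving one
   apical and one basal abundance per subject (the pairing unit is the
   subject; with 8 subjects the exact signed-rank test has a p-value floor
   of `2/2^8 = 0.0078`, which matches the cohort sizes the design implies);
2. computes the score `(1/n) sum_i log2((A_i + pn)/(B_i + pn))` — the log2
   geometric mean of per-subject ratios;
3. tests the per-subject log2 ratios against zero with the exact two-sided
   Wilcoxon signed-rank test;
4. BH-corrects across tested genes and calls polarization at `q < 0.25`.

### Exactness under ties and zeros

Zeros among the differences are dropped (the classical convention: a zero
carries no directional information) and tied absolute differences receive
mid-ranks. Doubling mid-ranks makes all rank scores integers, so the null
distribution of the doubled statistic over all `2^n` sign assignments is
computed by the standard count-generating polynomial recursion — exact for
any tie pattern, with no size cap and no normal approximation anywhere. The
two-sided p doubles the smaller tail (capped at 1). The rank-sum test used
for two-group comparisons enumerates the subset-sum distribution of the
combined mid-ranks the same way up to a combined n of 40, beyond which a
tie-corrected continuity-corrected normal approximation takes over (the
pipeline's own comparisons are all far below the cap). Genome-wide scans
cache null distributions by rank multiset, so the 2,000-gene fit costs
seconds.

Both tests are verified against brute-force enumeration oracles (all sign
vectors; all `C(N, n1)` subsets) for every n up to 12, including ties and
zeros, and against `wilcox.test(exact = TRUE)` on tie-free inputs.

## Zonal changes and the cross-species comparison

`zonal_change_test()` forms, per subject, the difference between the
tip-zone and base-zone log2 apical/basal ratios and applies the same exact
signed-rank machinery; BH is applied within this analysis separately (each
analysis family — polarization, zonal, interspecies, protein groups — gets
its own BH, as each asks a separate question of the data).

`interspecies_change_test()` compares human and mouse per-sample log2
ratios for each one-to-one ortholog pair by the exact rank-sum test. The
sampling unit is the subject-zone ratio (16 human vs 10 mouse in the full
design), not the pooled per-subject ratio: the test compares the two
species' samples, and with the pooled unit (8 vs 5) the rank-sum p-value
floor of `2/C(13,5) = 0.0016` would make the BH threshold of 0.2
unreachable for a handful of truly changed genes among a thousand — an
instructive discreteness trap of exact tests at small n. A gene is declared
changed only under the dual criterion: interspecies `q < 0.2` *and* minimum
species-specific polarization `q < 0.1` (the second arm ensures the change
is anchored by significant polarization in at least one species). Only
one-to-one orthologs are compared; ratio comparison is ill-defined under
gene-family expansion.

The same BH discreteness governs the `q < 0.1` arm: with 8 subjects, a gene
at the signed-rank floor has `q = m * 0.0078 / j`, where `j` is the number
of genes at the floor. The arm is attainable only when a sufficient fraction
of the transcriptome is strongly polarized — about 8% of tested genes at
the floor for `m = 1000`. This is a property of the method, not of an
implementation choice, and it is why the change-detection fixture in the
test suite plants its 5 flipped orthologs in a transcriptome with 15% truly
polarized genes.

## Proteomics

iBAQ tables are cleaned in the order: remove suspected contaminants and
proteins with fewer than 2 unique peptides; subtract the minimal iBAQ value
(global minimum by default — the alternative per-sample reading is exposed
via `per_sample_min`); drop samples with fewer than 1,000 identified
proteins; column-normalize. Left-censored missing values are imputed from a
down-shifted Gaussian in log space (1.8 SD below the per-sample observed
mean, 0.3 SD wide — the standard mass-spectrometry down-shift convention,
parameters exposed), seeded for reproducibility.

Differential abundance routes the normalized abundances through a
negative-binomial Wald test (DESeq2). A count model needs integers, so
normalized iBAQ is scaled by `1e6` and rounded — an explicit, documented
transformation of a continuous quantity into pseudo-counts; consequently
absolute significance counts from this step should be treated as
approximate (the spirit of the test is a dispersion-aware fold-change
assessment). Independent filtering is disabled so q-values are plain BH.
Group polarization (histones, ECM, mucins, SLC transporters, ...) uses the
exact rank-sum test of the group's log2 ratios against all other proteins.
`cytoplasmic_subset()` re-runs analyses after removing nuclear-only and
Matrisome proteins — the basal compartment captures residual nuclear and
stromal material, and conclusions should survive its removal.

## Concordance and the enterocyte classifier

mRNA and protein log2 ratios are related two ways: Spearman correlation on
genes above an expression floor, and a 2x2 sign-quadrant table
(apical/apical, apical/basal, ...) with one-sided hypergeometric enrichment
p-values given the margins. Genes with an exactly zero ratio have no sign
and are excluded from the quadrants (reported separately). The percent
concordant is `(AA + BB) / total` over all matched genes above the floor —
not only significant ones; both universes are defensible, and the
all-matched default is the more conservative headline.

Bulk LCM profiles mix cell types; enterocyte-specific genes give a cleaner
mRNA-protein comparison. The classifier takes a cell-type x gene signature
matrix (row-normalized so each cell type sums to 1) and declares a gene
enterocyte-specific iff `(E + pn)/(N + pn) > 2` and `E > 1e-5`, with E the
enterocyte expression, N the maximum across other cell types, and pn the
smallest positive entry of the matrix.

## smFISH statistics

Spot mode: spot-intensity sums are divided by segmented area, and per-pair
log2 apical/basal density ratios are summarized by mean and SEM. Intensity
mode: the matched background median is subtracted from each compartment's
median intensity; per subject, the per-cell log ratios are tested against
zero with *two* exact one-sided signed-rank tests (left- and right-tailed),
and the smaller p-value with its direction is kept; subjects are combined
with Fisher's method (`X = -2 sum log p_i ~ chi-square(2k)`). Taking the
minimum of two one-sided tests without doubling is mildly anti-conservative
(its null p is stochastically smaller than uniform); the procedure is
reproduced as practiced, with this property stated rather than silently
"corrected". Background subtraction clamps nonpositive intensities at
`1e-12` and flags the clamped cells rather than dropping them. Compartment
morphometry tests apical versus basal per-cell widths with the exact
rank-sum test and reports both mean and median width summaries, since
either may be the quantity of record.

## The synthetic-data generators

`simulate_lcm_rnaseq()` emulates the paired design: one apical and one
basal negative-binomial (gamma-Poisson) sample per subject and zone, with
basal library sizes scaled by `basal_depth_factor` (default 0.5, matching
the observed basal yield deficit). Polarized genes (default 10% at
|log2| = 1.5) receive constant-magnitude effects with signs balanced half
apical/half basal, and the two compartment relative-abundance profiles are
constructed to carry exactly equal total mass; together these make the
expected normalized ratio of every non-polarized gene exactly 1 and of
every polarized gene exactly `2^L` — so recovery bands measure the
statistics, not a generator bias. Defaults: `depth_mean = 1e5` UMIs
(typical post-QC LCM yields), `dispersion = 0.15` (bulk RNA-seq
overdispersion scale), gene abundances log-normal with sdlog 1.5 (spanning
the ~4 orders of magnitude of real transcriptomes).

The generators deliberately omit several features of real data: subject
(batch) effects beyond depth, correlated gene modules, compartment-specific
contamination (stromal material in basal cuts), and continuous zonation
along the villus (only the two-level tip/base contrast is modeled). Passing
recovery bands therefore demonstrates correctness of the statistical
machinery under the design's noise model, not robustness to every artifact
of real tissue.

`simulate_proteome()` draws log-normal iBAQ values around per-protein
means offset by the true log2 ratio, censors values below the
`proteome_detect_floor` abundance quantile (left-censoring, mirroring
detection physics), and adds contaminant rows and low-peptide rows for the
cleaning filters to remove. `simulate_signature_matrix()` constructs its
planted enterocyte-specific genes to satisfy the classifier rule *after*
row normalization, with non-planted genes capped below the 2-fold rule
margin, so the classifier round trip is exact by construction.
`simulate_fish_measurements()` adds a common additive background to
multiplicative log-normal signal noise with unit mean, so the expected
background-subtracted ratio equals the configured true ratio.

## Numerical choices and degenerate inputs

* All-zero signed-rank difference vectors return p = 1 with a message
  (degenerate, no information).
* All-zero samples abort normalization by name; an iBAQ table that is
  constant after minimum subtraction aborts with a degeneracy error.
* Depth thresholds are inclusive (a sample at exactly 10,000 UMIs is kept,
  since "below 10,000" is removed); the PCA depth filter is strict
  (more than 20,000).
* Genes absent from the biotype annotation are dropped conservatively and
  reported; duplicate gene ids are suffixed to keep join keys unique.
* Zero-variance genes are excluded from PCA scaling silently — they carry
  no ordination information.
* Spearman correlations use the asymptotic p (`exact = FALSE`) since tied
  ranks are ubiquitous in expression data.

## Problem sizes

The test suite and the acceptance script exercise the pipeline at 2,000
genes for the headline recovery bands (sensitivity >= 0.5 and FDR <= 0.35
at q < 0.25 under 10% truly polarized genes at |log2| = 1.5 with 8
subjects), 1,000 genes for the cross-species change fixture, 100-replicate
sweeps at 40 genes for the invariance properties, and exhaustive oracle
comparison for all exact-test sizes up to n = 12. These sizes were chosen
so each property is measured where it is informative: the recovery bands
need a genome-scale BH universe, while the algebraic invariances hold at
any size.

## Known limitations

* The DESeq2-on-pseudo-counts route makes protein significance counts
  sensitive to the (documented) scaling constant; treat them as ~10%-level
  approximate.
* The dual-criterion change detector inherits the BH discreteness floor
  discussed above; with fewer than ~8 genes at the rank-sum p floor it
  cannot fire at all.
* The min-of-one-sided Fisher combination overstates evidence under the
  null; its per-subject inputs are reported so a doubled variant can be
  computed trivially if desired.
* Orthology handling keeps only one-to-one pairs; paralog families are
  excluded rather than resolved.
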