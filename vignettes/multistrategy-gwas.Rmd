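---
title: "Multi-strategy GWAS for a quantitative trait: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-strategy GWAS for a quantitative trait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`multigwas` implements three association strategies for a quantitative
trait — the worked example throughout is average daily gain (ADG,
kg/day) in fattening beef cattle — plus the quality control, synthetic
data and reporting around them. This vignette is the package's account
of the statistics: the models and their assumptions, the parameters
that matter, what the simulator does and does not emulate, the
numerical choices, and known limitations.

## The trait

ADG is not measured directly: each animal is weighed at a handful of
ages and the trait is the ordinary-least-squares slope of weight (kg)
on age (days) over the fattening period (`adg_from_weights()`). Which
weighings constitute "the fattening period" is herd-specific, so the
age window is a parameter (`window =`) rather than a fixed rule; the
default uses every record.

## The shared mixed-model core

All three scans build on one mixed linear model:

    y = W v + u + e,   u ~ N(0, sigma_a^2 K),   e ~ N(0, sigma_e^2 I)

* `W` holds the intercept, categorical herd-management covariates (sex,
  birth year, calving season) and, for population structure, the top
  `k` genotype principal components (default `k = 3`; the structure
  covariate is named in the literature but its encoding rarely is, and
  genotype PCs are the standard choice).
* `K` is the VanRaden genomic relationship matrix over a random draw of
  markers (default 50,000; a draw rather than the full panel mirrors
  common practice at BeadChip scale and costs little accuracy). Dosages
  are centered by `2p` and the cross-product scaled by `sum(2p(1-p))`,
  so `diag(K)` averages about 1 and `sigma_a^2` is on the trait scale.
* Variance components come from an EMMA-style REML: the model is
  rotated onto an orthonormal complement of `span(W)` and the
  restricted likelihood optimized in one dimension over
  `delta = sigma_e^2 / sigma_a^2`. The rotation through an explicit
  complement basis (rather than eigenvectors of `S K S`) stays valid
  when `K` is low-rank, which any panel with fewer markers than samples
  produces. Because the restricted likelihood can be multimodal in
  `delta`, a 121-point coarse grid over `log(delta) in [-12, 12]`
  precedes a local refinement; an optimum at the interval edge is
  returned with a `boundary` flag and a warning, since it means one
  component is effectively zero. Heritability is reported as
  `h2 = sigma_a^2 / (sigma_a^2 + sigma_e^2)`.

**SNP scan.** Each marker is tested by generalized least squares under
`V = sigma_a^2 K + sigma_e^2 I` with the variance components *fixed at
the global fit* — the P3D/EMMAX approximation. This is exact only when
no single marker shifts the variance components appreciably, which
holds in the regime the method is meant for; `per_snp_reml = TRUE`
refits per marker for small panels. Wald statistics refer to chi-square
with 1 df. The variance explained by a marker is `2 p q beta^2 /
sigma_p^2` with `sigma_p^2` the sample phenotypic variance. The
genome-wide suggestive threshold `P < 1e-6` is a configurable default,
not a constant.

**Candidate markers stay in the kinship.** Markers being tested are not
excluded from `K`. On a genome-scale panel the cost is negligible, but
it matters at toy scale: if the panel is small, the tested marker is a
large share of `K`, the polygenic term absorbs its signal ("proximal
contamination") and power collapses. The power studies in the tests
therefore use panels of a few thousand markers so that no block exceeds
a fraction of a percent of `K` — a property real BeadChip panels have
by construction, not a tuning knob.

## Haplotype-block scan

1. **Pairwise LD** is estimated from unphased genotypes by a two-locus
   EM (only the double heterozygote is ambiguous). `D'` confidence
   intervals come from profiling the genotype-table likelihood over
   |D'| on a 101-point grid with allele frequencies plugged in — the
   likelihood-based interval that block partitioning expects.
2. **Partitioning** follows the Gabriel confidence-interval rule with
   the PLINK 1.7 defaults, all exposed as arguments: a pair is strong
   LD when CI-low >= 0.70 and CI-high >= 0.98, strong recombination when
   CI-high < 0.90; a span is a block when its outer pair is strong LD
   and >= 95% of informative pairs inside are strong LD; no block spans
   more than the 100 kb window. Candidate spans are ranked by physical
   length and accepted greedily without overlap, making the result
   deterministic. Blocks are named `Hap-<chr>-N<index>` in positional
   order.
3. **Phasing** is an EM over the haplotype pairs compatible with each
   sample's genotypes (enumeration bounded at 25 SNPs per block and 12
   heterozygous sites per sample; wider blocks should be split).
   Convergence is declared when the largest frequency change falls
   below 1e-6 (or 1,000 iterations); haplotypes below frequency 1e-4
   are pruned and frequencies renormalized. A `debug` mode asserts the
   observed-data log-likelihood is non-decreasing every iteration.
4. **Testing** regresses the trait on expected haplotype counts
   (posterior dosages — robust to phase uncertainty; the most probable
   diplotype is also recorded) by GLS under the global `V`, with the
   most frequent haplotype dropped as baseline. The block statistic is
   the squared Wald ratio of the largest-magnitude haplotype effect on
   1 df. With more than two haplotypes this max-over-effects statistic
   is anti-conservative as a pure significance test; it is the method
   being implemented, and the calibration test therefore uses
   two-haplotype blocks, where the maximum is just the single contrast.
5. **Variance explained** is the two-step statistic: least-squares
   haplotype effects, one-dimensional two-means clustering of the
   effects into a low group G1 and a high group G2 (centers initialized
   deterministically at the extreme effects), a per-sample 0/1/2 count
   of G2 haplotypes in the most probable diplotype, and
   `2 p q beta^2 / sigma_p^2` with `p`, `q` the G1/G2 frequency masses
   and `beta` the OLS slope of the trait on the count. With two
   equal-frequency haplotypes this reduces exactly to the biallelic
   formula. Blocks whose effects are all equal have no contrast and
   return 0 with a flag.

Block length is reported as `end - start` in bp, matching the
convention of the block tables this output format mirrors.

## Gene-based scan

Gene windows are the annotated gene body ± 50 kb (clipped at 1), SNPs
assigned by position in closed intervals; genes off the autosomes or
covered by fewer than 3 SNPs are dropped with counts reported. Per
gene, PCA runs on the column-centered (unstandardized, by default —
the "indicator" coding; a `standardize` flag switches) dosages and
keeps the smallest number of PCs whose cumulative explained-variance
proportion *strictly exceeds* 0.85; PC signs are fixed by making each
loading vector's largest element positive so results are reproducible.

The "phenotype" of the gene model is the GBLUP breeding value:
`u_hat = sigma_a^2 K V^-1 (y - W v_hat)` with `v_hat` the GLS solution,
equivalent to Henderson's mixed-model equations. Each retained PC is
regressed against the EBV; the per-PC statistic is the squared Wald
ratio (1 df) and the gene P-value is the minimum over its PCs — taken
over all PCs whatever their number, since with one PC the minimum is
the only P anyway; the rule is only genuinely ambiguous at exactly
two PCs, where the minimum over both is taken.

**Permutation threshold.** Each cycle permutes the phenotype labels
against the genotypes, recomputes every gene's min-P, and pools
`n_genes x n_perm` statistics; the cutoff is the
`ceiling(alpha * N)`-th smallest pooled value (at 23,856 genes and
1,000 cycles that is rank 238,560 of 23,856,000 — the exact
alpha-quantile rather than a rounded rank). Two schemes are provided:

* `scheme = "ebv"` (default): the EBV vector itself is permuted. Cheap
  and LD-preserving, but the EBV is a linear function of the genotypes
  through `K`, so it is *mechanically* correlated with intragenic PCs;
  permuting destroys that correlation, making the null slightly too
  easy to beat. At genome scale (tens of SNPs per gene out of hundreds
  of thousands in `K`) the effect is negligible; at desk scale it is
  visible.
* `scheme = "phenotype"`: the raw trait is permuted and pushed through
  the fixed GBLUP operator (`ebv_operator()`) each cycle — variance
  components are not refit, which keeps the cost at one matrix-vector
  product per cycle. This reproduces the mechanical dependence in the
  null and is the scheme the calibration checks use.

A second, subtler point: under a polygenic trait *no* gene is exactly
null — every gene's markers carry a sliver of the genetic signal
through the kinship — so calibration is assessed on traits simulated
with negligible heritability. BH q-values (`bh_fdr()`, a thin wrapper
over `stats::p.adjust`) accompany the permutation flag.

## Quality control and imputation

Markers: call rate >= 0.95, MAF >= 0.05 (strictly-less-than removal, so
MAF exactly 0.05 survives), Hardy-Weinberg exact-test P >= 1e-5. The
HWE test is the exact conditional test computed by the standard
recurrence over heterozygote counts — exact avoids small-count
pathologies and matches what PLINK does; the statistics are computed
once on called genotypes and the rules applied in call-rate → MAF → HWE
order so every removal has a single attributed cause. Samples with
missingness strictly above 10% are removed; marker rules run first
(the order is a convention — both reports are emitted so the other
order's counts can be read off).

Imputation is a deliberately simple frequency-based imputer: missing
dosages are drawn from Binomial(2, p-hat) per marker, seeded. It
preserves marginal allele frequencies and HWE but ignores LD entirely —
it completes the matrix for kinship construction; it is *not* a
phasing-grade imputer, and imputation accuracy is nowhere an analysis
target here.

## The synthetic-data generator

`sim_config()` defaults encode the study conditions the analyses
assume: ~1,000 animals; an LD-block panel (blocks of 5 SNPs spanning
20 kb, drawn from 4 founder haplotypes each, separated by 1 Mb so
between-block LD is nil by construction); expected MAF >= 0.05
everywhere; a trait with mean 0.98 kg/day, SD 0.16 kg/day and
narrow-sense h2 = 0.48; sex/birth-year/calving-season effects of a few
hundredths of kg/day; 1% missingness, completely at random. Planted
effects by default: one causal SNP at 0.05 kg/day per allele (about 4%
of variance at intermediate frequency), one causal haplotype at
0.10 kg/day per copy at founder frequency 0.20, and one three-SNP
"gene" at 0.02 kg/day per allele each.

The variance budget: fixed-effect variance comes off the top of
`trait_sd^2`; the remainder is split `h2 : (1 - h2)` between genetic
and residual; the polygenic component gets the genetic budget minus the
realized planted-causal variance (clamped at zero with a warning when a
deliberately extreme effect — e.g. the 0.45 kg/day haplotype power
scenario — exceeds it). The polygenic term is drawn with covariance
proportional to the VanRaden matrix of the simulated panel itself, so
estimation is well-posed and REML recovery is a meaningful test. All
randomness flows from one seed; identical configs are bit-identical.

What the simulator does **not** emulate: pedigree and family structure
(samples are unrelated founder draws, so `K` is near-identity plus
block noise), selection, genotyping error, missingness that depends on
genotype, LD *between* blocks, allele-frequency spectra skewed toward
rare variants, and multi-breed stratification beyond what the covariate
machinery can represent. Passing tests on this generator therefore
demonstrate correctness of the statistics under their own assumptions,
not robustness to the full mess of real cattle data.

## Numerical choices and degenerate inputs

* Monomorphic markers: flagged and skipped everywhere (P = 1 with a
  `degenerate` flag in scans; excluded from kinship with a count).
* Rank-deficient designs: aliased haplotype columns are dropped by the
  pivoted QR inside the GLS fit; estimates stay finite.
* P-values are floored at the smallest representable double rather
  than underflowing to zero.
* Probabilities in the D' likelihood grid are floored at 1e-12 before
  logs.
* Two-means clustering initializes at the extreme effects and breaks
  the (measure-zero) equidistant tie toward G1.
* The LD display classes use strict inequalities exactly as printed in
  the regional-plot convention (`>0.9, >0.7, >0.5, >0.3`, residual
  `<0.3`); a boundary value falls to the lower class.

## Problem sizes in tests and the acceptance script

The test suite and `scripts/acceptance.R` rerun the analyses at sizes
chosen to make each property measurable on one CPU in minutes:
heritability recovery uses 50 replicates at n = 1,000; the null scan
pools four 5,000-marker panels at n = 500; block-boundary recovery uses
n = 2,000 with 3 founders per block; the haplotype power scenario uses
15 replicates of a 40-block panel at n = 1,000; gene-scan calibration
uses 400 single-block genes at n = 200 with h2 = 0.05. Scenario
dimensions (panel large relative to any one block; near-null trait for
calibration) follow from the modelling points above, not from the test
outcomes.

## Known limitations

* The max-haplotype Wald statistic's 1-df reference is anti-conservative
  for blocks with many haplotypes (inherited from the method).
* The EBV-label permutation scheme is mildly anti-conservative whenever
  tested genes are a non-trivial share of the kinship panel; use
  `scheme = "phenotype"` in that regime.
* The binomial imputer must not be used where downstream analyses need
  LD-faithful imputed genotypes.
* `partition_blocks()` is quadratic per window and intended for
  chromosome-arm-scale inputs, not whole-genome BeadChips in one call.
* Exact PLINK `--blocks` output is not reproduced bit-for-bit; the rule
  set is Gabriel's CI method with PLINK defaults.
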