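---
title: "Methods: colony-level introgression estimation in polyandrous honey bees"
author: "beeIntrogress"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colony-level introgression estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beeIntrogress)
```

## Scope and model

`beeIntrogress` estimates C-lineage introgression into *Apis mellifera
mellifera* colonies from two kinds of evidence: pooled colony allele
frequencies (pool-seq of ~30 workers) analysed with frequency-based
ABBA BABA statistics, and diploid genotypes analysed with a
maximum-likelihood admixture model. A synthetic haplodiploid colony
simulator supplies data with the statistical structure both analyses
assume, so every estimator in the package can be exercised and calibrated
end to end without external data.

This vignette records the modelling choices, the tunable parameters and
their defaults, the numerical decisions, and what the synthetic
calibrations do and do not demonstrate about real data.

## The synthetic lineage and colony model

**Lineage panel.** Per site, an ancestral derived-allele frequency is drawn
uniformly on [0.05, 0.95]; each lineage then drifts under a Balding–Nichols
model: a descendant frequency is Beta-distributed around its ancestor with
an FST-like parameter F (`driftFrequencies()`). The panel holds four
populations: M (emulating *A. m. mellifera*), C1 and C2 (two subpopulations
of the C lineage, emulating *A. m. carnica* and *A. m. ligustica*, drifting
`C12` below a common C ancestor), and an outgroup. Defaults are
`MC = 0.30`, `C12 = 0.05`, `outgroup = 0.50`: genome-wide SNP
differentiation between the M and C honey bee lineages is strong (FST of
roughly 0.2–0.4 at informative markers) while the two commercial C
subspecies are far closer to each other, and the outgroup is a separate
species. Under this parameterization the expected Hudson FST between M and
the C ancestor equals `MC`, which the test suite verifies by Monte Carlo.

**Outgroup polarization.** A configurable fraction of sites (default 0.8)
is flagged "outgroup-fixed": there the outgroup carries the ancestral
allele at frequency exactly 0, and only such sites enter ABBA BABA
analyses. "Ancestral" is *defined* as the outgroup-fixed allele — the
convention the polarization step (`polarizeFrequencies()`) enforces by
flipping in-group frequencies wherever the outgroup is fixed for the
alternate allele. Real outgroup panels are finite samples, so "fixed"
there means "fixed in the sampled individuals"; the simulator's exact 0/1
is the idealization of that filter.

**Colonies.** A colony is a queen plus `n` haploid drone mates
(`ColonySpec`). Ancestry acts per site: each queen-haplotype or drone
allele is drawn from the C-donor frequency with probability equal to the
individual's ancestry proportion, otherwise from the M frequency. Workers
receive one queen gamete — haplotypes segregating independently per site,
i.e. free recombination, consistent with the very high recombination rate
of honey bees and with the package's block-based (not linkage-based)
variance estimation — and the complete haplotype of a drone chosen by the
patriline weights (uniform by default; skewed weights let one probe how
unrepresentative a single worker can be). The closed-form colony C
fraction is queen/2 + patriline-weighted drone mean/2
(`expectedColonyAncestry()`).

**Pooled sequencing.** Equimolar contribution is assumed: per site the
total depth is Poisson with the stated mean (default 40, the usual design
depth for colony pools) and the alternate read count is binomial with
success probability equal to the pool's true frequency (mean dosage / 2).
The number of drone matings is deliberately a free parameter: honey bee
queens mate with on the order of 10–20 drones, but reported numbers vary
widely, so no single value is baked in; examples and calibrations use 8.

**What the simulator does not emulate:** linkage disequilibrium along
chromosomes (sites are exchangeable; only the block structure used by the
jackknife is laid out), selection, reference bias, mapping or genotyping
error, and non-equimolar pooling. Calibrations passing on this model show
the estimators are correct and well-sized under their own assumptions;
they do not certify robustness to those unmodelled features.

## Filters

The filter sequence is fixed — biallelic, depth, site missingness, sample
missingness, then cross-dataset intersection — and every stage appends a
row to `filterLog()`. Choices the underlying procedure leaves open:

- Missingness thresholds (default 0.9) are **inclusive**: a site observed
  in exactly 90% of samples is kept.
- The depth filter works on the **per-site mean depth across samples**;
  the double-mean ceiling is twice the grand mean of those per-site means
  (a grand mean of 32.5 reproduces the familiar 5–65 band).
- Site identity for intersection is the full (chromosome, position, REF,
  ALT) tuple; position matches with mismatched alleles are dropped with a
  warning rather than silently paired.
- Pools and individuals are filtered separately and then intersected.
- Pool frequencies are AD_alt / DP; zero depth is missing, never zero.

## ABBA BABA statistics

With the outgroup ancestral, the frequency-weighted site-pattern sums are
ABBA = Σ (1−p₁)p₂p₃ and BABA = Σ p₁(1−p₂)p₃ — exactly the per-site
expectations obtained by enumerating all eight haploid allele
configurations, which the tests verify to 1e-12. Patterson's
D = (ABBA−BABA)/(ABBA+BABA); degenerate sites contribute equally to both
sums (cancelling in D) and are retained for block accounting.

**Blocks.** Jackknife blocks are contiguous runs of equal SNP count
(remainder spread one per block from the first), not equal genomic length:
equal weighting per block is what keeps the leave-one-out estimates
exchangeable when genotyping density varies. 10,500 sites in 20 blocks is
exactly 525 SNPs per block. The delete-one-block SE is
√((n−1)/n · Σ(θ₋ᵢ − θ̄)²) with Z = θ/SE and two-sided normal p. The
normal reference with 20 blocks is mildly anti-conservative (the exact
reference would be closer to a t with 19 degrees of freedom), which is
visible as an empirical size slightly above 0.05 in the null calibration;
the package keeps the conventional normal rule, which reproduces published
(Z, p) pairs exactly.

**f.** The admixture proportion compares the observed ABBA−BABA excess
S(p₁, p₂, p₃b) = Σ p₃b(p₂−p₁) to the excess under complete admixture,
obtained by substituting P2 with a second donor-lineage representative:
f = S(p₁, p₂, p₃b) / S(p₁, p₃a, p₃b). In the battery the substitute p₃a is
the lexicographically next donor colony after p₃ (a deterministic pairing,
logged per test); with a single donor colony the same vector fills both
slots and the battery warns that f is then biased upward. A negative mean
f is reported as-is with a warning, never truncated.

**f4-ratio.** α = f4(A,O;X,C) / f4(A,O;B,C) with
f4(W,X;Y,Z) = mean((p_W−p_X)(p_Y−p_Z)). The orientation is fixed by this
package as follows: **A and B are two representatives of the donor
lineage** (the sister pair whose shared drift the denominator measures),
C is a recipient-lineage reference, X the test population, and α is the
donor-lineage fraction of X's ancestry, reported with its complement 1−α.
X ≡ B gives α = 1 exactly; X from the recipient lineage gives α ≈ 0. Any
other assignment of the donor pair would put independent drifts in the
denominator and make the ratio undefined in expectation (the
implementation refuses |denominator| < 1e-12 rather than clamping).

**A known attenuation worth stating.** When the donor panel is the
*sister* subpopulation of the true donor (estimating C1-donor admixture
with a C2 panel), the denominator includes the panel's own within-
subpopulation drift while the numerator does not, attenuating f by roughly
the ratio of between- to within-C covariances — about 8% at the default
`C12 = 0.05`. The same-subpopulation panel is unbiased. This mirrors the
practical situation where *carnica*- and *ligustica*-based estimates of
the same colony differ slightly, and it is why the recovery calibration
holds both panels to ±0.05 rather than expecting exact agreement.

## The trio battery

Reference colonies are admitted at Q ≥ 0.99 to their own subspecies
cluster — a deliberately strict panel of low-introgression standards. Per
focal colony the battery runs the full mellifera × donor cartesian product
(72 tests for 6/6/6 panels), aggregates mean and SD of f per donor, and
classifies **"significant" only if every test in the donor group has
D > 0 and p < 0.05**; the strict all-combinations reading is what
reproduces the bundled survey's counts of 4 colonies non-significant for
both donors and 5 for *carnica* only. Undefined statistics in single tests
are recorded as NA (which classifies the group "nsi") rather than aborting
the battery. No multiple-testing correction is applied across colonies,
matching the procedure the battery emulates.

## The admixture model

The likelihood is the standard binomial admixture model:
ℓ = Σᵢⱼ gᵢⱼ ln(Σₖ qᵢₖ fₖⱼ) + (2−gᵢⱼ) ln(Σₖ qᵢₖ(1−fₖⱼ)). The package uses
multiplicative EM updates rather than quasi-Newton block relaxation:
simpler, provably monotone (asserted for every fit in the tests), and fast
enough at the panel sizes used here. Numerical choices: cluster
frequencies are clamped to [ε, 1−ε] with ε = 1e-6 to keep the likelihood
finite; Q rows are renormalized each iteration and must sum to 1 within
1e-8; convergence is declared when the log-likelihood improves by less
than 1e-6 (default) and `maxIter` caps runaway fits; unsupervised rows are
initialized from a Dirichlet(1) jitter under the given seed, supervised
rows are fixed to unit vectors; multiple restarts keep the best
likelihood. K = 2 is the analysis default (M vs C); the fit accepts K = 1
as the degenerate baseline so that cross-validation can compare it.

Cross-validation masks a fraction (default 1/folds) of observed genotype
entries, refits, predicts masked dosages as 2·Σₖ qᵢₖ fₖⱼ, and scores mean
squared error; the chosen K minimizes the error. Masking that would empty
a sample or site is redrawn with a warning; a masking fraction of zero is
refused as degenerate.

Pooled samples enter the genotype route through pseudo-genotypes: either
`round(2f)` or a thirds threshold rule. Both are provided because the
encoding is a modelling decision with no canonical answer; the rule used
is recorded in the object's metadata, never hidden.

## Calibration choices and problem sizes

The package's own calibrations (test suite and `scripts/acceptance.R`)
use: 10,000 sites and 20 blocks for D-test size (full-pipeline
no-gene-flow replicates — pure-M colonies at P1/P2, pure-C at P3, 40×
pools — 200 in the test suite, 400 in the reproduction script for a
tighter Monte-Carlo margin); donor fractions 0.1–0.4 for battery recovery against 6/6/6
panels; 10,000 sites and 10+10 supervised references for admixture Q
recovery; 2,000 sites and 200 colonies with 8 patrilines for the
pool-versus-single-worker comparison. These sizes make every property
measurable with comfortable Monte-Carlo margins while keeping a full run
in minutes on one core.

## Known limitations

- Sites are treated as exchangeable; with real linked data the block
  jackknife absorbs local correlation only as far as blocks exceed the
  correlation length.
- The f attenuation under sister-subpopulation panels (above) means
  cross-donor f values are not exactly comparable at high introgression.
- The admixture model assumes Hardy–Weinberg within clusters and unlinked
  sites; pooled pseudo-genotypes violate its sampling model and are
  provided for comparability, not as a recommended estimator — the
  ABBA BABA route is the frequency-native analysis.
- The EM fit finds local optima; supervised panels or multiple restarts
  are recommended in practice.
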