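---
title: "cfmix methods: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cfmix methods: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfmix)
```

cfmix dissects a plasma cfDNA sample that mixes up to three genomes —
donor-derived hematopoietic DNA after a bone-marrow transplant (A),
residual maternal DNA (B) and placental DNA from a donor-egg pregnancy
(C). This vignette is the package's own account of the underlying
models, the synthetic data they are exercised on, and the choices made
where the design was genuinely open.

## The capture panel and what the simulation emulates

All statistics index against a targeted capture panel: 679 autosomal
regions each carrying one biallelic SNP (concentrated on chromosomes 13,
18 and 21 — 222/221/194 — with 42 spread over the other autosomes), plus
30 dosage-only regions on each of ZFX and ZFY. Regions average 100 bp
(drawn Uniform(60, 140)); each SNP sits within the last 30 bp of its
region, where capture efficiency peaks. Coordinates are 0-based
half-open (BED convention) on synthetic scaffolds.

Population alt-allele frequencies default to Uniform(0.2, 0.5): mixture
panels select common, informative SNPs, and the generator keeps
frequencies away from the boundaries so every locus can be informative.
This is a deliberate, configurable idealization — no public frequency
spectrum exists for a panel of this design, and the *absolute* value of
frequency-dependent statistics (notably the unrelated-pair mrs baseline,
about 0.24–0.30 here) shifts with this choice even though every ordering
the package tests is preserved. A panel enriched for frequencies near
0.5 would raise all mrs values; published values on real data (unrelated
pairs around 0.45–0.7) are consistent with a commoner spectrum than the
default.

`simulate_pedigree()` draws founders per locus from Binomial(2, af)
(Hardy–Weinberg) and builds children by independent Mendelian
transmission. The case pedigree: the bone-marrow donor is a full sibling
of the mother by default (`donor_mode = "parent"` is available — the
clinical description pins only "first-degree relative", and the sibling
choice leaves the donor's sex free); the fetus is the child of an
unrelated egg donor and the father, hence genetically unrelated to the
woman carrying him.

Sequencing is simulated at the read-count level: per-locus depth
n ~ Poisson(depth) (a fixed-depth mode exists for exact tests), and
alt reads Binomial(n, p) with p = q(1 − ε) + (1 − q)ε, where
q = Σ w_k g_k / 2 is the mixture's template alt fraction and ε the
per-read substitution error (default 0.005, typical of hybrid-capture
data). Defaults follow the study conditions: plasma at 2500×, gDNA
samples at 500×, mixture weights (0.7264, 0.18, 0.0936).

Not modeled: GC/fragment-length bias, PCR duplication structure,
alignment artifacts, placental mosaicism (the placental component is the
fetal constitutional genotype), and probe thermodynamics. Tests passing
on this generator therefore demonstrate the *statistical* machinery —
identifiability at the stated fractions and depths — not robustness to
real-world technical noise.

## Sex-chromosome dosage and component fractions

Dosage is normalized against a known 46,XX calibration sample:
CN_X = 2·mean(ZFX)/ref, CN_Y = 2·mean(ZFY)/ref. A sample that is a
fraction m male DNA has CN_X = 2 − m, CN_Y = m, so the normalized shares
are ((2 − m)/2, m/2) and m = 2·y_share. This single model reproduces
both a 0.59/0.41 share split and an 82 % male-DNA fraction
simultaneously. Estimates of m outside [0, 1] (counting noise at the
boundary) are clipped with a logged warning rather than rejected.

Sex calls threshold m at t_low = 0.05 / t_high = 0.95 — far outside
binomial noise at panel depths (at 2500× and 30 regions the standard
error of m is well below 0.01) — anything between is reported as a
`mixed` sample with its m.

The placental fraction f is an *input*: clinically it comes from a
read-distribution predictor trained on reference cohorts, which is out
of scope here. Given (m, f) and the fetal sex, the component arithmetic
is exact; inconsistent inputs (an XY fetus with f > m) raise an error
rather than being silently clamped. `estimate_fractions_ls()` is the
self-contained alternative: minimize Σ(af_l − Σ w_k g_lk/2)² over the
simplex, solved by non-negative least squares (`pracma::lsqnonneg`)
followed by normalization. On noiseless input recovery is exact; at
2500× over 679 loci the error is well under ±0.02 per component.

## Mixture genotyping (pseudo-tetraploid / pseudo-hexaploid)

`deconvolve()` enumerates all 3^k genotype configurations per locus
(k = 2 or 3), scores each with the binomial read model above, applies
independent Hardy–Weinberg priors per component, and normalizes with
log-sum-exp. The priors deliberately ignore the true relatedness of the
components: relatedness is exactly what the downstream mrs analysis
measures, and encoding it in the prior would make that measurement
circular. A flat-prior mode exists for sensitivity checks.

Numerical conventions:

* MAP ties (possible at symmetric q) are broken toward the higher prior,
  then the lexicographically smallest configuration; ties are counted
  and reported via a message.
* Loci with zero depth are emitted as missing.
* Genotypes are only *emitted* (in `split_major_minor()` and
  `call_genotypes()`) when the MAP posterior reaches 0.9; below that a
  call is a near coin-flip and would pollute mrs denominators.

The two-component split labels the larger-weight component
`<sample>major`. The case study splits the plasma at weights
(1 − f, f) — the standard pseudo-tetraploid framing with the placental
fraction as the minor component — so the major row tracks the pooled
non-placental DNA and the minor row the fetus. The alternative split at
(m, 1 − m) (male pool vs residual maternal) was considered and rejected
as the default: it makes the minor row the *mother*, which discards the
fetal signal that the downstream paternity comparison needs.

Fitting a two-genome model to a three-genome sample forces wrong calls
wherever the pooled major genomes disagree. `split_major_minor()`
therefore applies a model-misfit filter: a two-sided binomial tail test
of the alt count under the MAP configuration's expected fraction
(default α = 1e-4) flags loci that no two-genome configuration can
explain — at 2500× a pooled-genotype disagreement sits ~9 SD from every
configuration — and sets them missing in both rows.

One identifiability limit is intrinsic to the case fractions and worth
knowing: with w_B = 0.18 ≈ 2 × 0.0936, a single maternal alt allele
shifts q by almost exactly the same amount as two placental alt alleles
(0.09 vs 0.0936), so some three-genome loci alias onto a wrong
two-genome configuration with a near-perfect fit that no filter can
detect. The surviving minor-row errors compress the gap between
"father vs plasma-minor" and the unrelated band; on the default
simulation the expected ordering holds, but the margin is small, and a
k = 3 deconvolution (which resolves the aliasing by modeling B
explicitly) is the structurally sound alternative whenever a donor
profile is available — in the default case study its per-component
concordance is ≥ 0.99 for all three genomes.

The MAF band-deviation diagnostic summarizes mixture evidence without
any model fit: a pure diploid genome's alt fractions concentrate in
bands at {0, 0.5, 1}; `maf_spectrum()` reports the fraction of
well-covered loci (default ≥ 50 reads) outside ±δ of those bands
(default δ = 0.1). A pure gDNA sample at 2500× scores ≈ 0; the
three-way case mixture ≈ 0.22.

## Relatedness: mrs, classification, MDS

For a pair of genotype vectors, shared loci are those called in both;
the mrs denominator keeps shared loci where **at least one** genotype is
non-reference, and the numerator counts identical genotypes among them.
The "at least one" reading was chosen over "both non-reference" because
the latter is non-monotone in relatedness: conditioning on both samples
carrying alternate alleles inflates the match rate of unrelated pairs
above that of parent-child pairs (verifiable by enumerating the nine
genotype-pair probabilities under Hardy–Weinberg). The strict mode
remains available as `mode = "both"` for sensitivity analysis.

Classification thresholds are not universal constants — the class means
depend on the panel's allele-frequency spectrum — so
`calibrate_thresholds()` simulates duplicate pairs (same genome, 1 %
independent per-locus genotyping error), sibling pairs and unrelated
pairs on the panel in use and places each threshold at the midpoint
between adjacent class means, warning when the classes overlap beyond a
5 % confusion tolerance. Deconvolved mixture components routinely fall
*between* bands (a minor row contaminated by aliasing is part fetus,
part noise); the `margin` parameter of `classify_relationship()` lets
such records be reported as `ambiguous` rather than forced into a
class.

The IBS distance is 1 − (shared alleles)/(2 · shared loci), and the MDS
embedding is classical (Torgerson) scaling: double-center the squared
distances, eigendecompose, scale the top-k eigenvectors by √λ. IBS
distances need not be Euclidean; negative eigenvalues are truncated to
zero with a warning, the standard practice.

## The end-to-end case study

`run_case_study()` wires everything together on six simulated samples
(mother WBC / plasma / oral mucosa, father WBC / plasma, fetal
amniocytes). The mother's WBC sample defaults to 100 % donor genotype
(the transplant fully engrafted), with a `residual_host_fraction` knob
for sensitivity runs; father plasma is pure father (no transplant). All
randomness derives from one master seed via fixed offsets, so a config
reproduces its artifact bundle byte-for-byte; every output file is
stamped with a hash of the config.

Problem sizes: the default study runs the full 739-region panel with
plasma at 2500×; threshold calibration uses 60 pedigree replicates
(100 in the acceptance checks); the package's stochastic tests use
20–100 replicate simulations per property. A reduced configuration
(100 loci, depth a few hundred) exercises the whole pipeline in well
under ten seconds and is used as the smoke test.

## Known limitations

* Fraction arithmetic assumes exactly the three stated components with
  known karyotypes; a vanishing twin or donor mosaicism would violate
  it.
* The k = 2 split's minor row is intrinsically degraded by the aliasing
  described above whenever the mixture truly has three genomes.
* mrs values are comparable only within a panel; thresholds must be
  recalibrated when the frequency spectrum changes.
* The generator's idealizations (no GC bias, no mosaicism, Poisson
  depth) mean observed concordances are upper bounds on what identical
  settings would achieve on real libraries.
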