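---
title: "Parent-of-origin association methods in poefam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parent-of-origin association methods in poefam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poefam)
```

## The problem

Genome-wide association studies of unrelated individuals estimate a
*marginal* per-allele effect: the average over alleles inherited from the
mother and from the father. If a locus is subject to a parent-of-origin
effect (POE) — for instance through genomic imprinting — the two parental
effects differ, and the marginal estimate is diluted toward their average.
Detecting POE therefore requires family data: a pedigree deep enough to
decide, for each allele of each genotype, which parent transmitted it.

`poefam` implements the two complementary family designs for this question:

1. **Quantitative trait in extended pedigrees.** Allele origins are assigned
   by pedigree phasing; the log-transformed trait (BMI in the motivating
   application) is then regressed separately on the dosage (standard test),
   on the paternally inherited allele, and on the maternally inherited
   allele, and the two parental slopes are compared.
2. **Case-parent trios.** For an affected heterozygous child the
   transmitting parent of a designated allele is often determined by the
   parental genotypes alone; asymmetry between paternal and maternal
   transmission counts is tested against a 50:50 binomial null (the
   parental asymmetry test, PAT).

## Input conventions

Genotypes, pedigrees and phenotypes use the PLINK text dialects (PED/MAP/
FAM) plus a header-led TSV for phenotypes. Dosages count the **minor**
allele as determined from the observed allele frequencies; a frequency tie
is broken by lexicographic order of the allele symbol and recorded in the
variant metadata, so every downstream orientation is deterministic.
Coordinates are 1-based, strand is taken as given (forward-strand input is
assumed; no strand flipping is attempted), and the missing codes are `"0"`
for alleles and parent ids and `NA`/`-9` for phenotypes. A phased VCF with
`|`-separated GT (interpreted as `paternal|maternal`) is accepted as
pre-phased input and bypasses the phaser.

## SNP quality control

Variants are screened before phasing with the standard array filters, all
strict inequalities: missing rate `< 0.05`, exact Hardy–Weinberg `P >
1e-4`, `MAF > 0.01`. A variant sitting exactly on a boundary fails. The
HWE test is the conditional exact test — the probability of every
heterozygote count compatible with the observed allele counts is computed
by a stable ratio recurrence, and the two-sided p-value sums all
configurations no more probable than the one observed. The exact test was
chosen over the chi-square approximation because candidate-region panels
are small and the exact version is the accepted practice for array QC; at
the permissive 1e-4 threshold the two rarely disagree. By default all
genotyped individuals enter the HWE test, relatives included; a
founders-only option exists for users who prefer an unrelated subset, but
it is off by default because the downstream filters are deliberately
permissive and founders-only counts are much noisier in small cohorts.

## Parental-origin phasing

Origin assignment uses deterministic single-marker Mendelian constraint
propagation. Per variant and family, each individual's ordered
(paternal, maternal) allele pair starts from the set of pairs compatible
with its observed dosage (all four pairs if untyped) and is shrunk to a
fixpoint under two rules applied alternately:

* a child's paternal (maternal) allele must be one the father (mother) can
  carry, given the parent's own remaining pairs;
* a parent must be able to supply each child's remaining allele options on
  the corresponding side.

Homozygotes phase outright. A heterozygous child with one homozygous
parent is forced (`trio-forced`). Information also travels through
*untyped* members: two homozygous grandparents determine an untyped
parent's transmissible allele and thereby phase the grandchild
(`propagated`), and a child's resolved allele feeds back into its parent's
own phase. Whatever remains ambiguous at the fixpoint — canonically the
child–father–mother all-heterozygous configuration with no outside
information — is left `unresolved`. Because every restriction is logically
implied by the observed genotypes, the phaser never guesses: on simulated
data every assigned allele equals the gene-dropping truth, which the test
suite asserts. The trade-off is abstention; multi-marker haplotype
phasers resolve more sites at the cost of occasional errors, and this
package deliberately keeps unresolved sites as missing data instead of
imputing them.

Mendelian inconsistencies (e.g. a dosage-2 child of a dosage-0 parent) set
the family's cells at that variant to unresolved and are logged per
family; they never abort a run, mirroring how family studies treat sparse
genotyping error.

Founders have no recorded parents, so their own allele origins are never
assigned; they contribute transmissions only. Consequently the per-variant
**unphased rate** is computed over origin-eligible individuals (those with
at least one recorded parent) — the natural denominator, since founders
can never be resolved by any method. Variants with an unphased rate
`>= 0.30` (inclusive bound) are removed before association testing.

## Association tests and the slope comparison

BMI is ln-transformed before regression to approximate normality of the
residuals. Each test is an ordinary least-squares fit with intercept,
adjusted for age, sex and T2D status (T2D as a 0/1 covariate, to avoid
confounding by the disease's own BMI association). Complete cases are used
per SNP, so `n` varies across SNPs with missingness. Relatedness is *not*
modelled (no kinship mixed model); this matches the single-marker
regression practice the package mirrors and is listed under limitations.

The paternal and maternal predictors are the 0/1 transmitted alleles.
Some toolchains instead double each parental allele to fake a diploid
genotype; doubling halves the slope and leaves the p-value unchanged, so
results are reported on the natural 0/1 scale with `beta_doubled_scale =
beta/2` alongside for comparability with doubled-input outputs.

Parental slopes are compared with the Wald statistic
`t = (b_pat - b_mat) / sqrt(se_pat^2 + se_mat^2)`, referred to the
standard normal. At the sample sizes where this comparison is meaningful
(hundreds of phased individuals) the difference from a t reference is
negligible; a `df` override is available. The two estimates come from
separate regressions on the same trait, but with independently segregating
parental alleles their sampling covariance is of order `b^2/n` and
ignorable at realistic effect sizes — the test's type-I error under equal
nonzero parental effects is checked by simulation in the test suite.

Multiple testing uses the Bonferroni rule `alpha / (m * 3)` for `m` SNPs
times three test modes; p-values are reported unadjusted.

## The parental asymmetry test

For a heterozygous affected child, the parent that transmitted the
designated allele is determined whenever not both parents are
heterozygous: with designated-allele dosages `gf`, `gm`, transmission is
paternal iff `gf >= 1 & gm <= 1` and not conversely. Double-heterozygous
parent pairs are ambiguous and excluded — the transmitting parent is
genuinely undefined there — and Mendelian-impossible combinations are
excluded and counted. All offspring are assumed affected unless an
affection column says otherwise, reflecting ascertainment on an affected
child.

Under no asymmetry the paternal count is `Binomial(n, 1/2)` given `n`
informative transmissions. The two-sided p-value is twice the smaller
exact tail, capped at 1. The doubling rule was fixed (rather than the
minimum-likelihood rule `binom.test` uses) because it is deterministic,
symmetric in the two counts, and indistinguishable from the alternative at
the count magnitudes this design produces; the suite cross-checks it
against direct pmf summation. The p-value is invariant to which allele is
designated (counts swap between parents, since a heterozygous child who
received the minor allele from one parent received the major from the
other); the major allele is the default for reporting.

Exact binomial p-values are discrete: with ~70–270 informative
transmissions the attainable p-values have atoms of a few percent, so the
null p distribution is sub-uniform (conservative) rather than exactly
uniform. The calibration tests therefore assert the rejection rate at 5%
within a binomial band and the absence of anticonservative excess, not
pointwise uniformity.

## Linkage disequilibrium

With phase known, `r²` needs no EM: paternal and maternal haplotypes of
origin-eligible individuals are pooled, haplotypes unresolved at either
site are dropped pairwise, and `r² = D²/(pA pa pB pb)` is computed from
direct haplotype counts. Monomorphic variants yield `NA` with a warning,
never 0.

## The synthetic-data generator

Every statistical property above is tested against data whose truth is
known, produced by gene dropping: founder haplotypes at Hardy–Weinberg
proportions, one uniformly chosen allele transmitted per parent, true
(paternal, maternal) origins stored for **all** individuals (founders get
latent origins so phenotype effects apply uniformly) before missingness
is overlaid. Defaults emulate the motivating adult cohort: 141 families,
27 candidate SNPs at MAF 0.3, a 98.7% genotyping rate, age ~ N(45.4,
17.2²) clamped to 18–90 years, 59% female, 9% T2D prevalence, and
`ln(BMI)` with intercept 3.16 and residual SD 0.2, centring BMI near
26 kg/m². The trio generator draws parents at Hardy–Weinberg, gene-drops
the child, and retains trios whose child is affected under
`baseline_risk * rr_pat^X_pat * rr_mat^X_mat` (capped; a logistic link is
available), defaulting to 705 trios. One mandatory integer seed drives
everything; the phenotype stage derives its stream from the same seed so
a configuration is fully reproducible.

What the generator does **not** emulate: linkage disequilibrium between
candidate SNPs (an optional two-SNP mode with a target r² exists purely to
exercise the LD module), genotyping error, population structure,
assortative mating, and age/cohort structure in allele frequencies.
Passing tests therefore demonstrate correctness of the statistical
machinery under clean Mendelian transmission, not robustness to every
artefact of real array data.

## Problem sizes used by the checks

The simulation-based checks run at sizes chosen to make their tolerance
bands meaningful while staying lightweight: effect recovery and dilution
use 2,500 nuclear families (≈5,000 phased offspring) at `beta_pat = 0.04`,
`sigma = 0.15`; phasing soundness uses 500 three-generation families;
PAT null calibration and the slope-comparison type-I error each use 2,000
replicates at 200 trios / 200 individuals. Coverage and calibration bands
are ±0.02 around their nominal values, the 2-SD binomial width at these
replicate counts.

## Known limitations

* Single-marker phasing abstains at fully heterozygous configurations;
  ~10% of eligible genotypes stay unresolved at MAF 0.3 in nuclear
  families, and parental-mode regressions lose those observations.
* No kinship adjustment in the regressions; related individuals inflate
  the effective sample size slightly.
* The PAT here is the plain binomial version; it does not model parental
  genotype main effects or separate maternal-genotype effects from
  imprinting (log-linear likelihood frameworks do, at the cost of more
  assumptions).
* Sample-level QC (per-individual call rate, heterozygosity, relatedness
  verification) is out of scope; inputs are assumed to have passed it.
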