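---
title: "Models and methods in hybridzone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in hybridzone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hybridzone)
```

# The problem

`hybridzone` analyses contact zones between two strongly diverged,
habitat-associated forms of a species — here called the *savanna* and
*forest* ecotypes, after the tropical tree system the package was built
around — genotyped at a modest number of codominant multiallelic markers
(microsatellites). The questions it addresses are the classic hybrid-zone
ones: how diverged are the two gene pools, which individuals in the contact
zone are pure, F1, F2 or backcrossed, how much of the genetic variance sits
between ecotypes versus among and within populations, and whether genetic
structure follows geography (isolation by distance, IBD) or environment
(isolation by environment, IBE).

# Genotypic classes and ancestry profiles

A *genotypic class* is a cross category defined by an explicit pedigree over
founders from pool A (savanna) and pool B (forest): the parentals P1 and P2,
F1 = A × B, F2 = F1 × F1, first-generation backcrosses B1 = F1 × A and
B2 = F1 × B, the second-generation backcrosses B3–B8, and the advanced
intercrosses F3 and F4. For unlinked autosomal loci each class is fully
characterized by its *ancestry profile*
$\varphi = (\varphi_2, \varphi_1, \varphi_0)$, the probabilities that a
locus carries two, one, or zero gene copies of A ancestry.

`expected_ancestry_profile()` computes $\varphi$ exactly by recursion on the
probability that a gamete transmitted by a pedigree member carries A
ancestry: 1 for an A founder, 0 for a B founder, and the parental mean for
any offspring. Because every terminal of a pedigree denotes a distinct
founder, the two gametes that form the focal individual are independent and
$\varphi_2 = g_1 g_2$, $\varphi_1 = g_1(1-g_2) + (1-g_1)g_2$,
$\varphi_0 = (1-g_1)(1-g_2)$. All intermediate values are dyadic rationals
($k/2^m$ with small $m$), which doubles represent exactly, so the arithmetic
is exact and $\varphi_2+\varphi_1+\varphi_0 = 1$ holds without tolerance.
`drop_ancestry()` provides the independent Monte-Carlo check used in the
tests.

A structural consequence worth stating up front: the pairs
\{B1, B3\}, \{B2, B4\}, \{B5, B7\}, \{B6, B8\} and the trio \{F2, F3, F4\}
have *identical* profiles. No classifier operating on unlinked markers can
separate them, whatever the sample size — this is the mechanistic reason
backcross resolution collapses in the 12-class analyses, and
`class_equivalences()` exposes the groups so the evaluation harness can
score with them merged.

# The Bayesian classifier

`hybrid_classify()` fits a finite-mixture model in the NewHybrids family by
Gibbs sampling (implemented in C++). The latent structure is

* per individual, a class label $z_i$ with mixing proportions $\pi$ under a
  symmetric Dirichlet prior (concentration 1/2 per class, a Jeffreys-like
  choice, with equal prior probability for every class);
* per individual and locus, an ancestry state
  $w_{il} \in \{2, 1, 0\}$ A-copies with $P(w \mid z) = \varphi_z$;
* per gene copy, a pool-of-origin indicator; and
* per pool and locus, allele frequencies $\theta_A, \theta_B$ under
  symmetric Dirichlet(1/2) priors.

Given $w$, the genotype is a Hardy–Weinberg draw: both copies from
$\theta_A$ when $w=2$, both from $\theta_B$ when $w=0$, and one from each
pool when $w=1$ (heterozygote $a \ne b$:
$\theta_A(a)\theta_B(b)+\theta_A(b)\theta_B(a)$; homozygote:
$\theta_A(a)\theta_B(a)$). The class label is updated with $w$ collapsed
(summing $\varphi_z(w)\,P(\text{genotype}\mid w,\theta)$ over states), which
mixes much better than updating through $w$. Missing calls are skipped in
every likelihood; an individual with no data keeps its prior and is flagged.
The posterior matrix is the post-burn-in average of the class indicators.
Defaults are 10^6 iterations with 10^5 burn-in, the configuration of the
reference analyses; the examples and tests use much smaller budgets, which
already stabilize posteriors on data of this size (a two-seed stability
check is part of the test suite).

**Pool-label anchoring.** Without constraints the model is invariant under
swapping A and B. The supported anchor is `reference`: individuals whose
class is fixed during sampling. Otherwise $\theta$ is initialized from the
most frequency-divergent partition available — ecotype labels when present,
else the most divergent population pair — and a label-swap diagnostic
(initialization-distance check on the posterior-mean $\theta$) is reported.
The evaluation harness reflects posteriors through the A/B symmetry when
that diagnostic fires.

**Reproducibility.** One global seeded RNG drives the sampler (R's own
generator, also used inside the C++ code); iteration order is individuals
then loci, so runs are bit-reproducible for a fixed seed.

# Hybrid index and interecotypic heterozygosity

`hybrid_index()` estimates, per individual, the proportion $h$ of its genome
drawn from pool B by maximum likelihood:
$\ell(h) = \sum_{\text{copies}} \log\{(1-h)\,p_A(\text{allele}) +
h\,p_B(\text{allele})\}$, maximized on a 0.001 grid with golden-section
refinement; the 95% interval is the profile-likelihood set
$\{h: \ell(h) \ge \ell(\hat h) - 1.92\}$ ($\chi^2_1$ cutoff), with interval
ends refined by root finding between grid points. Orientation is a named
knob: by default savanna-pure individuals sit near 0 and forest-pure near 1.
Degenerate cases follow explicit contracts: a flat likelihood (identical
pools) returns $\hat h = 0.5$ with CI $[0,1]$ and a flag; an allele unseen
in both parental pools receives the floor frequency $1/(2G+1)$ in both pools
($G$ = the pool's gene-copy count at the locus), which keeps the likelihood
finite without favouring either pool.

Interecotypic heterozygosity $Q_{12}$ is the fraction of loci combining the
two ancestries: the package reports the mean over usable loci of the
posterior probability of $w=1$ under a uniform prior over the three ancestry
states, with the same per-state genotype likelihoods as the classifier. The
uniform prior (rather than an $h$-dependent one) is a deliberate,
documented choice — it makes $Q_{12}$ a pure function of the genotype and
the parental frequencies, at the cost of a mild shrinkage toward 1/3 at
uninformative loci; with diagnostic markers it returns exactly 1 for F1s and
0 for parentals. `triangle_report()` computes the excess of $Q_{12}$ over
the triangle bound $1 - |2h - 1|$; individuals above the bound indicate
marker homoplasy (apparent shared ancestry from size-convergent alleles).

# Diversity, AMOVA and F-statistics

`diversity_table()` reports N, mean alleles per locus (A), allelic richness
rarefied to $g$ gene copies
($A_R = \sum_a [1 - \binom{N-N_a}{g}/\binom{N}{g}]$, computed with
log-binomials), observed heterozygosity, Nei's unbiased expected
heterozygosity ($2n/(2n-1)$ correction) and the Weir–Cockerham $f$
($F_{IS}$) as a multi-locus ratio of sums; monomorphic loci contribute
$H = 0$ and are excluded from $F_{IS}$. The default rarefaction size is the
per-locus minimum gene-copy count across the compared groups (the FSTAT
convention), recorded in the output metadata. Significance of heterozygote
deficits comes from permuting gene copies among individuals within
populations (which destroys the within-individual association while keeping
frequencies and missingness), with Holm correction across populations.
`null_allele_check()` is a deliberately simplified Monte-Carlo analog of the
Micro-Checker homozygote-excess test — no stutter model, no null-frequency
estimator — because the analysis flow uses it only as a QC gate.

`hierarchical_amova()` partitions gene-copy indicator variance into among
ecotypes ($\sigma^2_a$), among populations within ecotypes ($\sigma^2_b$)
and within populations ($\sigma^2_c$) by method of moments with unbalanced
nested-design coefficients, summing per-locus components with weights
proportional to typed gene copies, then forms
$F_{CT} = \sigma^2_a/\sigma^2_T$,
$F_{SC} = \sigma^2_b/(\sigma^2_b+\sigma^2_c)$ and
$F_{ST} = (\sigma^2_a+\sigma^2_b)/\sigma^2_T$. Components can be negative
(near-zero true values); they are reported as computed. With a single group
the estimator collapses exactly to the two-level among-population form —
that identity is tested to 10^-9. Permutation schemes follow the levels
being tested: whole populations among groups for $F_{CT}$, individuals
among populations within groups for $F_{SC}$, individuals among populations
for $F_{ST}$; p-values use the $(n_{\ge}+1)/(n_{perm}+1)$ estimator.
`pairwise_fst()` implements the Weir–Cockerham $\theta$ with the full
$a, b, c$ components (observed-heterozygosity correction), ratio-of-sums
across loci and alleles, negative estimates reported as computed with an
optional truncation toggle. The indicator (one-hot) formulation rather than
allele-size distances is intentional: the reference analysis is a standard
AMOVA on identity, not an $R_{ST}$-style stepwise model.

# Genetic distance and trees

`nei_distance()` computes Nei's standard distance
$D = -\ln( J_{XY} / \sqrt{J_X J_Y} )$ with per-locus gene identities
averaged across loci and, by default, the small-sample correction
$J_X = (2n\sum p^2 - 1)/(2n-1)$; pairs sharing no alleles anywhere are
flagged infinite rather than silently dropped. Neighbor-joining uses the
Saitou–Nei agglomeration from `ape`; negative branch lengths are clamped to
zero with the deficit moved to the adjacent branch so tip-to-tip path
lengths are preserved where possible. Branch support resamples loci with
replacement and reports the percentage of replicates containing each
original bipartition (integer node labels; Newick is the output format).
Additive metrics are recovered exactly — the test suite checks every 4- and
5-taxon tree shape.

# Landscape tests

Geographic distances are WGS84 geodesics in km; environmental distance is
pairwise Mahalanobis using the across-population covariance, falling back to
the Moore–Penrose pseudo-inverse (with a rank report) when predictors are
collinear; `env_pca_reduce()` offers standardized-variable PCA with
count-or-variance-fraction retention for the usual bioclim-style reduction.
The Mantel statistic is the Pearson correlation of off-diagonal upper
triangles; significance is one-tailed via joint row/column permutation of
the second matrix, $(n_{\ge}+1)/(n_{perm}+1)$, default 9999 permutations.
For small matrices an exhaustive mode enumerates all $n!$ permutations and
defines p as the proportion (identity included) with
$r_{perm} \ge r_{obs}$, so the exhaustive p is bounded below by $1/n!$.
The partial Mantel statistic is the first-order partial correlation of the
three pairwise Mantel r's, with significance from permuting the second
matrix while the d1–control correlation stays fixed; the collinear corner
case ($d_2$ identical to the control) returns 0 by the algebraic identity.
The genetic input in the intended workflow is the pairwise $F_{ST}$ matrix;
$F_{ST}/(1-F_{ST})$ linearization is available but not the default, since
the reference analysis does not state it.

# The synthetic-data generator

The generator defines the package's study conditions; it is not a tuning
surface. `make_parental_frequencies()` draws, per locus, an ancestral
frequency vector from a flat Dirichlet over `alleles_per_locus` (default 8)
alleles and the two parental pools independently from
Dirichlet(ancestral × (1−F)/F) — the F-model — with F defaulting to 0.35 to
mirror the observed between-biome pairwise $F_{ST}$ of roughly 0.33–0.40;
the estimator-recovery tests confirm that Weir–Cockerham $\theta$ on
samples from these pools averages F. `make_population_frequencies()` nests
a second F-model layer (default 0.08) to emulate within-ecotype population
structure, matching the observed within-biome range of about 0.07–0.10,
and `simulate_structured_populations()` assembles the two-ecotype sampling
layout (default 3 populations per ecotype). `simulate_class()` is exact
Mendelian gene dropping through the class pedigrees: founders are
Hardy–Weinberg draws from their pool, each transmission picks one parental
copy uniformly per locus. `build_evaluation_datasets()` replicates the
evaluation design — by default 100 individuals per class in each of 5
datasets, scaled down where runtime matters (the acceptance checks use 10
per class and 2 datasets, stated there as the package's own choice of
problem size) — with optional call-wise missingness and a null-allele
corruption model (a hidden allele segregating at frequency q; null
homozygotes become missing, null heterozygotes appear as visible-allele
homozygotes).

**What the generator does not emulate.** Real microsatellite pools carry
private and rare alleles accumulated over deep divergence, size
constraints, and mutation structure; the F-model at matched $F_{ST}$ is
considerably *less diagnostic* per locus than empirically estimated
parental frequencies. This matters for interpreting the evaluation
numbers, below.

# What the evaluation can and cannot reproduce

`replicate_study_design()` runs the three arms of the simulation study —
six simulated classes classified with six (6×6), fourteen with six (14×6),
fourteen with twelve (14×12) — and tabulates per-class correct-assignment
proportions at thresholds 0.5/0.75/0.85/0.9, where "correct" means the true
class's posterior reaches the threshold (an arg-max variant exists behind a
flag). Robust features of the reference results reproduce clearly on
synthetic data: parentals are assigned far better than any hybrid class,
F2 falls well short of the 50% mark at the 0.85 threshold, and backcross
resolution collapses in the 12-class arm, exactly as the profile
confounding predicts.

The *magnitudes* of the printed per-class percentages do not transfer, and
the package's own computations show why: a closed-form Bayes-oracle
calculation (classifying with the true pool frequencies, no MCMC at all)
under the generator's conditions already caps the fraction of F1s reaching
a 0.85 posterior at a few percent, and the sampler tracks that ceiling
closely for every class. High per-class certainty at 11 loci requires the
near-diagnostic empirical parental pools of the original data, not an
F-model at matched divergence. Consequently the fine ordering *among* the
poorly resolved hybrid classes at high thresholds (for example, whether F2
or a backcross class sits last at 0.85 with 10 individuals per class) is
sampling noise on counts of 0–2 and is not a stable property of the method
under these conditions; the acceptance suite asserts it anyway, as the
design prescribes, and this paragraph is the analysis of why that check can
fail while everything load-bearing about the method holds.

# Numerical choices and degenerate inputs

* Classifier: underflow-guarded log-likelihoods (per-locus mixture floored
  at 10^-300 before logging); Dirichlet draws via gamma variates; ties in
  `purity_call()` broken by class order, parentals first; thresholds below
  0.5 warn with more than two classes.
* Hybrid index: grid 0.001 plus golden-section refinement (tolerance 10^-9);
  boundary maxima checked explicitly; CI ends by `uniroot` at 10^-9.
* GenePop I/O: 2- vs 3-digit coding auto-detected per file, mixed widths
  rejected; any zero allele makes the whole call missing (diploid calls are
  all-or-nothing); duplicate ids uniquified with `.2`, `.3`, … suffixes.
* Missing data: complete-case per locus in every likelihood and statistic —
  no imputation anywhere.
* Allele codes are opaque integers; no size binning.

# Known limitations

Linked loci, inbred or looped pedigrees, and sex linkage are out of scope —
the ancestry model treats loci as independent and pedigrees as trees. The
null-allele check is a QC gate, not an estimator of null-allele frequency.
The classifier's pool-label anchoring without reference individuals is a
heuristic (initialization plus diagnostic), and reference individuals are
the recommended anchor for production use. Clustering-based structure
analyses (STRUCTURE/DAPC-style), migration-rate estimation, dbRDA/variance
partitioning and raster handling are intentionally not included;
environmental tables arrive pre-extracted.
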