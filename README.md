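# hybridzone

Hybrid-zone analysis of codominant multiallelic markers (microsatellites)
for two-ecotype systems: a savanna and a forest gene pool meeting in an
ecotone, with individuals of mixed ancestry in between. The package is
aimed at population geneticists who need, from one genotype table, the full
chain of a classical hybrid-zone study: marker QC, diversity statistics,
hierarchical AMOVA and F-statistics, genetic-distance trees, Bayesian
assignment of individuals to pedigree-defined genotypic classes, hybrid
index and interecotypic heterozygosity, Mantel-based isolation-by-distance
and isolation-by-environment tests, and a gene-dropping simulator to
evaluate how well any of it can work at the available marker resolution.

## The models at the core

**Genotypic classes.** Each cross category (P1, P2, F1, F2, backcrosses
B1–B8, F3, F4) is described by its per-locus ancestry profile
φ = (φ₂, φ₁, φ₀), the probabilities of carrying 2, 1, or 0 gene copies of
savanna ancestry at an unlinked locus, computed exactly from the cross
pedigree (`expected_ancestry_profile()`).

**Bayesian classification.** `hybrid_classify()` fits, by Gibbs sampling, a
mixture model in which each individual has a latent class z with
P(w = ancestry state at a locus | z) = φ_z, and conditional on w the gene
copies are Hardy–Weinberg draws from latent parental allele-frequency pools
θ_A, θ_B; mixing proportions and frequencies carry symmetric Dirichlet(1/2)
priors. The output is a per-individual posterior probability over classes,
and `purity_call()` applies assignment thresholds (0.5/0.75/0.85/0.9 in the
standard workflow).

**Hybrid index.** `hybrid_index()` maximizes
ℓ(h) = Σ log{(1−h)·p_A(allele) + h·p_B(allele)} over gene copies, with 95%
profile-likelihood intervals (χ²₁ cutoff), plus interecotypic
heterozygosity Q₁₂ (the fraction of loci combining both ancestries) and
triangle-bound diagnostics.

The surrounding statistics are the field's standard estimators:
Weir–Cockerham F_IS and θ, three-level AMOVA (F_CT / F_SC / F_ST) with
level-appropriate permutation tests, rarefied allelic richness, Nei's
standard distance with sample-size bias correction, neighbor-joining with
locus bootstrap, and simple/partial Mantel tests with Mahalanobis
environmental distances.

## Worked example

Simulate two diverged parental pools (F-model divergence 0.35, 11 loci, the
package's standard study conditions), a cohort of pure and hybrid
individuals, classify them, and estimate hybrid indices for the ecotone:

```r
library(hybridzone)
set.seed(42)
pools <- make_parental_frequencies(sim_config(), seed = 42)
gt <- gt_rbind(
  simulate_class(pools, class_registry()$P1, 20, "cerrado"),
  simulate_class(pools, class_registry()$P2, 20, "forest"),
  simulate_class(pools, class_registry()$F1, 5, "ecotone", id_prefix = "ecoF1"),
  simulate_class(pools, class_registry()$F2, 5, "ecotone", id_prefix = "ecoF2"))

fit <- hybrid_classify(gt, standard_class_sets("six"),
                       iterations = 100000, burn_in = 10000, seed = 1)
summary(fit, threshold = 0.85)
#> assignments at threshold 0.85:
#> lab
#>         F1         P1         P2 unassigned
#>          3         21         17          9

est <- triangle_report(hybrid_index(gt_subset(gt, which(gt$pop == "ecotone")),
                                    pools, "A", "B"))
est
#> hybrid index estimates for 10 individuals (0 flat)
#>    individual  h_hat ci_low ci_high   q12 n_loci_used  flat triangle_excess
#> 1     ecoF1_1 0.5826  0.297   0.843 0.556          11 FALSE           0.000
#> 2     ecoF1_2 0.5977  0.324   0.839 0.626          11 FALSE           0.000
#> 3     ecoF1_3 0.4250  0.155   0.727 0.513          11 FALSE           0.000
#> 4     ecoF1_4 0.4572  0.191   0.741 0.605          11 FALSE           0.000
#> 5     ecoF1_5 0.6886  0.386   0.928 0.531          11 FALSE           0.000
#> 6     ecoF2_1 0.4502  0.176   0.759 0.435          11 FALSE           0.000
#> 7     ecoF2_2 0.6087  0.314   0.864 0.373          11 FALSE           0.000
#> 8     ecoF2_3 0.6947  0.376   0.936 0.411          11 FALSE           0.000
#> 9     ecoF2_4 0.5477  0.246   0.859 0.289          11 FALSE           0.000
#> 10    ecoF2_5 0.0909  0.000   0.451 0.296          11 FALSE           0.115
```

Reading the output: 38 of 40 pure individuals are recovered as P1/P2 at the
0.85 threshold, 3 of the 5 F1s reach 0.85 for F1, and the rest land in
"unassigned" — at 11 moderately diverged loci, later-generation hybrids
rarely reach high posterior certainty, which is itself a finding the
package's evaluation harness quantifies. The ecotone hybrid indices sit
near 0.5 with wide intervals; F1s show higher Q₁₂ than F2s, and one
individual (`ecoF2_5`) drifts toward the savanna corner with a small
triangle excess.

Real data enter through `read_genepop()` / `read_genotype_csv()` plus
`read_sample_sheet()`; `run_pipeline()` drives the whole chain from a
config list and writes TSV tables, a Newick tree and a provenance manifest.

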