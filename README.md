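# ssrdemog

Microsatellite phylogeography and demographic inference for structured
mountain-tree populations — written around the classic silver-fir
(*Abies alba*) study design: ~45 populations of ~30 diploids genotyped at 8
nuclear SSR loci plus 3 fully linked chloroplast SSRs, sampled along a
west–east mountain gradient.

The package covers the full analysis chain:

* **I/O and QC** — GENEPOP read/write; null-allele frequencies per locus ×
  population by the Dempster EM under Hardy–Weinberg with one unobservable
  allele; the discard rule *null frequency > 0.05 in more than half the
  populations*; chloroplast haplotype assembly.
* **Diversity** — unbiased gene diversity `H_e = n/(n−1)(1 − Σp²)`,
  effective allele number, unique-allele proportion, inbreeding `F_i = 1 −
  H_o/H_e`, exact rarefied allelic and private allelic richness
  (`AR(g) = Σ[1 − C(N−N_i, g)/C(N, g)]`), and a dosage PCA at the
  individual level.
* **Differentiation** — pairwise Weir–Cockerham θ (F_ST) and Slatkin R_ST
  (allele-size variance components), the allele-size permutation test of
  phylogeographic signal (R_ST against size-shuffled `pR_ST`),
  isolation-by-distance regressions on haversine distances with
  Mantel-style permutation, and locus-bootstrapped neighbor-joining
  population trees.
* **Coalescent ABC** — an Rcpp backward-time structured coalescent with
  merge/admixture/resize events and generalized stepwise mutation
  (step = 1 + Geometric(P)); four divergence/admixture scenarios for
  Alps / West Pyrenees / East Pyrenees / admixed demes; reference tables,
  LDA + polytomous-logistic model choice with error calibration on
  pseudo-observed datasets, local-linear (logit-transformed) parameter
  posteriors, posterior-predictive checks on held-out statistics, and the
  mutation-rate-free population-size-change ratio θ₀/θ₁ = N₀/N₁.
* **Clusters and environment** — the Evanno ΔK cluster-number statistic,
  representative-population selection from ancestry (Q) matrices, a Pearson
  correlation screen with an empirical-Bayes local false discovery rate,
  variance inflation factors, and forward-stepwise BIC model selection.
* **Synthetic data** — study-shaped generators (genotypes under known
  demography, clinal Q matrices, 19 × 4 bioclimatic tables with planted
  effects, cluster-run tables) so every stage is testable end to end with
  recorded truth.

## A worked example

Simulate a hierarchical-split dataset (Alps split first, then East/West
Pyrenees, then secondary contact), run model choice and estimate the split
times:

```r
library(ssrdemog)
set.seed(1)

truth <- list(mu_nu = 5e-4, P_nu = 0, mu_cp = 1e-4, P_cp = 0,
              N1 = 5000, N2 = 5000, N3 = 5000, N4 = 5000,
              NA1 = 5000, NA2 = 5000, NA3 = 5000, NA4 = 5000,
              Nanc = 5000, T1 = 28000, T2 = 24000, T3 = 22000,
              Ta = 15000, Tb = 15000, Tc = 15000, Td = 15000,
              r1 = NA, r2 = 0.5)
obs <- summary_stats(simulate_dataset("S2", truth, n_dip = 25))

ref <- build_reference_table(n_per_scenario = 20000)   # ~4 min
mc <- abc_model_choice(ref, obs)
round(mc$logistic, 3)
#>    S1    S2    S3    S4
#> 0.202 0.290 0.294 0.214
round(mc$direct, 3)
#>    S1    S2    S3    S4
#> 0.249 0.269 0.241 0.241

post <- abc_parameter_posterior(ref, obs, "S2")
post$summary["T1", ]
#>   median     mode     q025     q975
#> 33413.18 32022.26 20801.49 56103.55
theta_ratio_posterior(post, "PyrE")[c("mode", "p_gt1")]
#> $mode
#> [1] 0.771
#> $p_gt1
#> [1] 0.484
```

The scenario probabilities are nearly flat — with 8 nuclear and 3 linked
chloroplast loci the four divergence scenarios are only weakly separable,
and the rejection (direct) estimate puts the generating hierarchical split
slightly ahead. The 95% credible interval on the oldest split
(20,801–56,104 generations) covers the generating value of 28,000, and
`generations_to_years(28000)` converts such an estimate to 840,000–1.12
million years at the 30–40-year generation time. The θ-ratio readout for
the Eastern deme has `P(ratio > 1) = 0.48` with mode near 1 — correctly
reporting demographic equilibrium, since these data were simulated without
a size change; values above 1 indicate expansion since the resize time.

Diversity and differentiation work on any `geno_dataset`, whether simulated
or read from GENEPOP:

```r
ds <- read_genepop("genotypes.gen", cp_loci = c("pt71936", "pt30141"))
diversity_stats(ds, "nuclear", g = 50)
fst_matrix(ds, "nuclear")
allele_size_permutation_test(ds, n_perm = 10000)
```

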