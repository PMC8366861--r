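---
title: "Models and methods behind ssrdemog"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ssrdemog}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrdemog)
```

`ssrdemog` implements the statistical workflow of a mountain-conifer
microsatellite phylogeography study: from raw co-dominant genotypes to
diversity and differentiation statistics, from there to coalescent-based
demographic inference by approximate Bayesian computation (ABC), and finally
to proxy models relating genetic variation to bioclimatic gradients. This
vignette explains the models, their assumptions, the tunable parameters and
their defaults, and the design choices made where the method literature
leaves an implementation genuinely open.

## Data model

A `geno_dataset` holds diploid nuclear microsatellite (nuSSR) genotypes and
haploid chloroplast (cpSSR) haplotypes for individuals grouped into
populations. Allele codes are positive integers, stored exactly as read —
fragment sizes in base pairs for laboratory data, repeat counts for
simulated data — with the locus' `allele_unit` recording which. Conversion
to repeat counts (needed by size-based statistics such as R_ST) happens only
at the point of use, through each locus' motif length. Missing data are `NA`
throughout and are excluded from every count; a half-missing diploid
genotype is rejected at construction. In firs, chloroplasts are paternally
inherited through pollen, so the three cpSSR loci behave as one fully linked
haploid locus; the package treats their combination as a haplotype.

## Null alleles and the locus filter

Null alleles inflate apparent homozygosity. `estimate_null_alleles_em()`
fits, per locus and population, the Hardy–Weinberg model with one
unobservable allele by the Dempster EM: apparent homozygotes *ii* are a
mixture of true homozygotes (probability $p_i^2$) and null heterozygotes
($2 p_i p_0$), and the all-null class is unobserved. Because that class is
invisible, the default likelihood is the truncated multinomial (each
observed-class probability divided by $1 - p_0^2$); the EM augments the
data with the expected number of unobserved null homozygotes. Whether
missing genotypes should instead be *counted* as null homozygotes is a
genotyping-pipeline question the data cannot answer, so it is an option
(`missing_as_null`), off by default. The log-likelihood is checked to be
non-decreasing at every iteration; defaults are `tol = 1e-8` on the
log-likelihood and `max_iter = 10000`.

`filter_loci_by_null_freq()` then discards a locus when its estimated null
frequency exceeds 0.05 in strictly more than half of the populations — the
standard quality rule for SSR panels of this kind; both the threshold and
the population fraction are arguments.

## Diversity statistics

Per population and locus-averaged: allele number $N_A$; unbiased gene
diversity $H_e = \frac{n}{n-1}(1 - \sum_i p_i^2)$ with $n$ observed gene
copies; effective allele number $N_{Ae} = 1/(1 - H_e)$ using the unbiased
$H_e$ (the naive $1/\sum p_i^2$ is available by flag). The bias-reduced
form can nominally exceed the observed allele count in very small samples,
so the per-population table caps $N_{Ae}$ at $N_A$ — effective alleles
cannot outnumber actual ones. The unique-allele proportion $A_u$ counts
alleles carried by exactly one individual of the population (a homozygote
carrier still counts once) over the distinct alleles observed there; it is
computed within the population only, with cross-population exclusivity
covered by private allelic richness. The inbreeding coefficient is
$F_i = 1 - H_o/H_e$ per locus and $1 - \sum H_o / \sum H_e$ multilocus.

Allelic richness is standardized for sample size by rarefaction:
$AR(g) = \sum_i \left[1 - \binom{N - N_i}{g} / \binom{N}{g}\right]$, the
expected allele count in a random draw of $g$ gene copies, computed with
log-space binomial coefficients; private allelic richness multiplies each
allele's presence probability in the focal population by its absence
probability in $g$-copy subsamples of every other population. Defaults
follow the study design: $g = 50$ copies for nuclear loci and $g = 22$ for
chloroplast haplotypes.

The individual-level ordination is a centered PCA on allele dosages (0, ½, 1
per allele for diploids; 0/1 for haplotypes) — the default of the standard
R genetics toolkits — rather than a correspondence analysis; unit-variance
scaling is a flag. Missing dosages are imputed by the population mean,
which keeps every individual in the analysis and is neutral for
between-population structure.

## Differentiation and phylogeographic signal

`pairwise_fst()` implements Weir & Cockerham's 1984 estimator: per-locus,
per-allele variance components (among populations / among individuals
within / within individuals) are summed across alleles and loci before the
final ratio, which weights loci by their information content. Haploid
chloroplast data use the analogous two-level components. The test suite
holds this estimator to $10^{-10}$ agreement with an independently coded
nested-ANOVA implementation.

`pairwise_rst()` is Slatkin's size-based analogue: one-way ANOVA components
of repeat counts with unequal group sizes, summed across loci. Because
R_ST uses allele size where F_ST uses allele identity, R_ST exceeding F_ST
indicates that sizes retain mutational memory — phylogeographic signal
under stepwise mutation. `allele_size_permutation_test()` formalizes this:
sizes are shuffled among the allelic states within each locus (identities
preserved), R_ST is recomputed, and the one-sided p-value is
$(1 + \#\{pR_{ST} \ge R_{ST}\})/(n_{perm} + 1)$. The default permutation
count is 10,000; tests and examples use fewer.

Isolation by distance is an OLS regression of the pairwise statistic's
lower triangle on great-circle distances (haversine, 6371-km sphere), with
significance by jointly permuting population labels of the statistic matrix
(a Mantel-type scheme); the F_ST- versus R_ST-slope difference is tested
under the same joint permutations. Raw F_ST on raw kilometers is the
default response; `s/(1-s)` and log-distance are flags, since the source
analyses do not fix a transform.

Population trees are Saitou–Nei neighbor joining on the F_ST matrix (via
`ape`); outgroup taxa are simply extra rows of the distance matrix.
Support values come from resampling loci with replacement — the only
exchangeable unit behind a distance-matrix tree — recomputing the matrix
and tree, and tallying bipartitions of the observed tree.

## The coalescent simulator

The simulator is a continuous-time structured coalescent run backward in
time, in units of generations, over four sampled demes — the Alps, the
Western and Eastern Pyrenees, and the admixed central Pyrenees. Each deme
carries a gene-copy number $G$: $2N$ for nuclear loci and $N$ for the
chloroplast (one paternally transmitted copy per individual; a multiplier
flag exposes other effective sizes). Within a deme, each lineage pair
coalesces at rate $1/G$; three event types modify the deme structure
backward in time: `resize` (piecewise-constant size change), `admixture`
(each lineage of the child deme joins one parent with probability $r$, the
other with $1-r$), and `merge` (a divergence seen backward). The
continuous-time approximation replaces the discrete Wright–Fisher
generations, which is standard and accurate for $N$ in the thousands.

Mutations are dropped on the resulting gene tree as a Poisson process of
rate $\mu$ per generation under the generalized stepwise model (GSM): each
mutation changes the repeat count by $\pm k$ with
$k = 1 + \mathrm{Geometric}(P)$ and equiprobable sign, so $P = 0$ recovers
the strict single-step SMM. Repeat counts reflect at a floor of 2 (an
allele cannot lose its repeat structure); there is no upper bound by
default. The three chloroplast loci are mutated independently on a single
shared gene tree, which is what full linkage means here. Under a single
panmictic deme and SMM, simulated equilibrium heterozygosity matches the
Ohta–Kimura closed form $1 - 1/\sqrt{1 + 8N\mu}$ within Monte-Carlo error —
this is an acceptance-level check.

## Scenarios and priors

Four demographic scenarios describe the origin of the four demes: a simple
three-way split with later contact (S1); a hierarchical split — Alps first,
then East/West Pyrenees, then contact (S2); and two variants in which one
Pyrenean lineage is itself of admixed origin (S3, S4). All scenarios allow
a population-size change on each terminal branch (times `Ta`–`Td`), which
is what the expansion/contraction inference rests on. Priors follow the
study: event times Normal(25000, 12500) and sizes Normal(5000, 2500), both
truncated positive (a floor of 10 avoids degenerate coalescent rates);
nuclear mutation rate log-uniform on $[10^{-4}, 10^{-3}]$ and chloroplast
on $[10^{-8}, 10^{-3}]$ per locus per generation. Orderings
($T_1 > T_2 > T_3$, resizes below the youngest divergence) are enforced by
rejection; the truncated normals themselves are drawn by inverse-CDF, so
prior sampling is exact and vectorized. Where the source left a prior
unstated, the defaults are the conventions of the DIYABC family: GSM
parameter $P \sim U(0, 0.9)$, admixture rates $U(0.001, 0.999)$; both are
arguments of `prior_spec()`. A single ancestral size parameter covers the
root and intermediate branches — with 11 loci there is little information
to separate deeper sizes, and it keeps the parameter vector comparable
across scenarios. The 18-bp-indel chloroplast locus is simulated as an
ordinary stepwise locus on its own motif; its low observed variant count is
within reach of the wide chloroplast rate prior. Per-locus rate
heterogeneity is off by default.

## Summary statistics and the ABC machinery

Per marker class, the catalog has four single-deme statistics (mean allele
number, mean genic diversity, mean allele-size variance, mean
Garza–Williamson $M$) and four pairwise ones (gene-copy Weir–Cockerham
$\theta$, pooled-pair diversity, $(\delta\mu)^2$, shared-allele distance) —
80 numbers over 4 demes and 6 pairs. No single statistic subset is canonical for this design, so the
fitting set is configurable. The default fits 20 nuclear statistics — $H_e$ and $M$ per
deme, $\theta$ and $(\delta\mu)^2$ per pair — and holds everything else
out for posterior-predictive checking (the check must use statistics the
fit never saw). Two calibration findings fixed this default. First, the
local-linear posterior adjustment is estimated on the ~200 retained
simulations, and regressing on 40–80 statistics makes the adjusted
credible intervals undercover badly (T3 coverage dropped to 0.75–0.85 in
pod studies); with ~20 statistics coverage is 0.95–1.00. Second,
chloroplast statistics are excluded from the default because the
chloroplast rate prior spans four orders of magnitude, so most simulated
chloroplast statistics sit near zero and a few are huge — including them
distorts the Euclidean retention step. The `prior_scenario_check()` rank
test (two-sided rank of each observed statistic among the simulations,
with a PCA projection) replicates the screening step used to pick adequate
statistics.

Model choice standardizes the fitting statistics by the reference table's
mean and SD, retains the 1% of simulations nearest the observation
(Euclidean), and reports both the retained-set scenario proportions and a
polytomous logistic regression on linear-discriminant axes with
Epanechnikov weights in distance, evaluated at the observation. Confidence
intervals come from parametric draws of the regression coefficients; a
scenario is declared *recovered* when its point probability exceeds every
other scenario's upper CI. Error rates are calibrated on pseudo-observed
datasets (pods) drawn per scenario from the 1% of its rows closest to the
observation, each re-classified with its own row excluded; type I is the
per-scenario miss rate, type II the rate at which other scenarios' pods are
absorbed, and the posterior error rate the mean probability mass placed on
wrong scenarios.

Parameter posteriors use the Beaumont local-linear adjustment with a logit
transform: each parameter is mapped onto its prior support (the observed
prior range, slightly padded, since normal priors are unbounded above),
logit-transformed, regressed on the standardized statistics over the
retained set with Epanechnikov weights, residual-adjusted to the observed
point and back-transformed. Point summaries are the weighted median, a
kernel-density mode (Gaussian kernel, Silverman bandwidth) and weighted
2.5/97.5% quantiles. A singular design falls back to the rejection
posterior, flagged. Estimator quality over pods is summarized by mean
relative bias, relative RMSE, 50/95% coverage and the factor-2 fraction.

The population-size-change readout is the ratio
$\theta_0/\theta_1 = N_0\mu / N_1\mu = N_0/N_1$ of current to pre-resize
scaled diversity; with mutation rate constant in time it is independent of
the unknown rate — doubling $\mu$ in the posterior draws leaves it
untouched by construction. Its mode is computed on the log scale, the
natural support of a ratio, which also keeps the expansion/contraction
readout exactly antisymmetric under swapping "current" and "past". Calendar
dates multiply generations by the 30–40-year sexual-maturity interval of
silver fir, reported as an interval.

## Cluster number and the environment stage

`evanno_delta_k()` computes $\Delta K = |\bar L(K+1) - 2\bar L(K) +
\bar L(K-1)| / \mathrm{sd}(L(K))$ from replicate clustering runs — the
mean-based form of the Evanno statistic, as compiled by the standard
harvester tools, since replicates at different $K$ are not paired. The
representative-population rule picks, per cluster, the population with the
highest ancestry coefficient, plus a contact-zone representative whose
maximum coefficient is closest to 0.5 (contact-zone populations in this
system sit near $Q \approx 0.45$); an exclusion list supports the duplicate analysis with
next-best populations.

The association stage screens all genetic × environment Pearson
correlations, converts them to $z = \mathrm{atanh}(r)\sqrt{n-3}$, and
estimates a local false discovery rate with a theoretical N(0,1) null: the
marginal density by Gaussian kernel, the null proportion $\pi_0$ by central
matching, $\mathrm{lfdr}(z) = \pi_0 f_0(z)/\hat f(z)$ clipped to $[0,1]$
and optionally made monotone in $|z|$ by isotonic regression. This is a
deliberate re-implementation of the estimand with simpler machinery than
the Grenander-based original, and it is validated against analytic mixture
truths in the tests; below 50 tests it falls back to Benjamini–Hochberg,
flagged. Variance inflation factors are $1/(1-R_j^2)$; model selection is
forward stepwise under $BIC = n\ln(RSS/n) + k\ln n$ with ties broken by
candidate order, stopping at the first non-improving step, and the final
model is refit for coefficients, p-values and adjusted $R^2$. One caveat
the tests make explicit: at 45 populations the best-of-many selection bias
of forward search admits noise variables at a non-trivial rate — the
parsimony guarantee of BIC is a large-$n$ property.

## The synthetic-data generators

`generate_study_like_dataset()` arranges populations (default 45 of 30
diploids, 8 nuclear + 3 chloroplast loci) on a west–east longitude axis
spanning about 4 degrees — the extent of the Pyrenees — by carving
same-cluster populations out of the hierarchical-split demes; the truth
record keeps every generating value. `generate_q_matrix()` plants a
logistic cline of western ancestry in longitude; `generate_env_table()`
emits 19 bioclimatic variables × 4 periods plus geography, with chosen
variables tied to a target vector at a specified correlation;
`generate_cluster_runs()` builds likelihood tables with a concave elbow at
the true cluster number. All generators are pure functions of
(configuration, seed).

What the synthetic data deliberately do **not** emulate: within-cluster
isolation by distance (populations of a cluster are exchangeable draws
from one deme), genotyping artifacts other than null alleles, linkage
among nuclear loci, selection, and post-divergence migration — the ABC
framework itself assumes none, which is a known source of divergence-time
underestimation. Passing tests therefore validate the statistical
machinery, not the realism of any particular dataset.

## What the desk scale can and cannot resolve

Two honest limits of the analysis at the working scale deserve stating,
because the tests make them visible. First, the four scenarios are only
weakly separable: at a hierarchical-split truth with closely spaced times
(28,000 / 24,000 / 22,000 generations), the generating scenario is a
boundary case of the admixture scenarios (S3 with $r_1 \to 1$, S4 with
$r_1 \to 0$) and close to the simple split (when $T_1 \approx T_2$), so
pseudo-observed datasets scatter their votes across scenarios — the same
weak separation that full-scale analyses of this design report as large
type I error. Second,
a 10-fold population expansion is carried by the simulator (an oracle ABC
that knows every other parameter detects a recent expansion with
probability near 1) but the rejection-plus-local-linear machinery at 200
retained simulations recovers it only partially; decisive
size-change posteriors of the kind full-scale analyses report arise at
50-fold larger reference tables, or for stronger expansions. The
equilibrium readout — the 95% ratio envelope containing 1 for
constant-size data — is reliable at the desk scale.

## Problem sizes and numerical choices

The package's working scale for the ABC study is a 4 × 20,000-row
reference table with 25 diploids per deme, the scale at which the
acceptance checks run; the original million-row-per-scenario scale is a
configuration change, not a code change. Tolerance is fixed at the 1%
nearest simulations. Rarefaction uses exact log-space binomial arithmetic;
the EM stops on a 1e-8 log-likelihood change; NJ tie-breaks follow `ape`;
permutation p-values always carry the +1 correction. Random draws go
through R's RNG everywhere, including the C++ simulator, so a single
`set.seed()` makes any pipeline reproducible.
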