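---
title: "Co-occurrence network guilds: models, assumptions and numerical choices"
author: "guildnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-occurrence network guilds: models, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## What the package models

Shotgun metagenomic profiling yields taxon-by-sample count tables that are
*compositional*: each sample's counts are a multinomial draw from an
unobserved community, so relative abundances are constrained to sum to one
and naive correlations between taxa are distorted by the closure.  guildnet
implements the analysis chain that turns such tables into ecological
statements: which taxa co-vary (a compositionally robust correlation
network), how those taxa organise into densely connected clusters
("guilds"/modules), how much of that network is realised inside each
individual sample (per-sample subnetwork topology), and how module
abundances and topological properties relate to clinical indicators such as
the estimated glomerular filtration rate (eGFR) in a longitudinal
transplant-style cohort.

## The generative model and its simulator

Every downstream stage is validated against a simulator whose model is
exactly the one the correlation estimator assumes: per sample, latent
log-abundances are multivariate normal with a block covariance (blocks of
`module_sizes` taxa share correlation `within_r`, cross-block pairs
`between_r`, background taxa are independent); the exponentiated vector is
closed to a composition and counts are drawn multinomially at a fixed depth.
Structural zeros are added as independent Bernoulli masking.  This makes the
estimand of the correlation step well defined, so recovery tests have an
exact ground truth (`SyntheticTruth`).

Default scales were chosen once as typical of genus-level metagenomic
tables: log-means spread over about three natural-log units, unit log-scale
standard deviations, sequencing depth 1e5 and structural-zero rate 0.1 (the
depth and sparsity of real tables vary widely; these are conventions, not
estimates).  The cohort generator plants a per-sample attribute — the
Shannon entropy of the composition — by *tempering*: for a target H it
solves for the exponent beta such that the entropy of the renormalised
p^beta equals H (entropy is strictly decreasing in beta, so `uniroot` on
beta in [1e-4, 60] finds the unique root).  Targets follow a quadratic in
the group's time rank plus N(0, 0.05) inter-individual jitter, which
reproduces the U-shaped ("first decreasing and then increasing") diversity
trajectories that the trend-fit stage is meant to detect.  Groups off the
time gradient (a healthy-control arm) use the rank-0 value.  The default
cohort design mirrors a transplant study's shape: a control group, a
pre-transplant baseline, and five follow-up timepoints with 5, 8, 9, 10 and
3 samples.

What the simulator does *not* emulate: taxon-specific mean-variance
relationships, phylogenetic structure, batch effects, and compositions whose
zero pattern depends on abundance (zeros here are missing-at-random).
Passing recovery tests therefore demonstrate correctness of the algorithms
under the stated model, not robustness to every property of real data.

## The correlation network

The correlation stage is the SparCC estimator built from log-ratio
variances: `t[i,j] = var(log(x_i/x_j))` is closure-invariant and zero
exactly for proportional taxa.  Under the sparsity approximation that most
pairs are uncorrelated, `t[i,j] ~ omega_i + omega_j` yields a linear system
for the basis (log-scale) variances `omega`, from which
`rho[i,j] = (omega_i + omega_j - t[i,j]) / (2 sqrt(omega_i omega_j))`,
clamped to [-1, 1].  Strongly correlated pairs violate the approximation, so
the pair with the largest |rho| above 0.1 is excluded from the system and
the system re-solved, iterating **until no pair exceeds the threshold**.  We
deliberately do not cap this at a small fixed number of rounds: with
block-structured communities (k blocks of b taxa there are k·b(b-1)/2
strongly correlated pairs) a 10-round cap measurably biases cross-block
correlations towards -0.3 at n = 500, while iterating to convergence removes
the bias (recovery RMSE drops from ~0.17 to ~0.04 in our tests).  Two
safeguards keep the system well posed: a feature always retains at least
half of its partners (and never fewer than two), and a non-positive solved
variance is replaced by the feature's clr variance (derived from `t`) rather
than a tiny floor — a tiny floor makes the rho ratio explode into a clamped
±1, which poisons permutation nulls.

Known limitation: when *every* taxon belongs to one of two large correlated
blocks, the community is two anti-correlated closure halves and the sparsity
assumption fails globally; no exclusion schedule fixes that (the classic
10-round variant is equally biased there).  Realistic tables contain
background taxa, and all recovery claims here are made for such shapes.

For count input the estimator averages over 20 per-sample Dirichlet
posterior resamples (shape = counts + 1, hence strictly positive fractions);
for relative input a single pass is run with a pseudocount of 1e-6 of the
column mass on zeros.  Edge significance uses a permutation bootstrap: each
replicate permutes every taxon's values independently across samples
(destroying association, preserving margins) and re-estimates rho; the
two-sided pseudo-p is `(1 + #{|rho_b| >= |rho_obs|})/(1 + B)` with add-one
correction, and Benjamini–Hochberg adjustment runs over the family of all
unordered pairs.  Note an interaction worth knowing: with `m` pairs in the
family and `k` true edges, the smallest achievable q is roughly
`m/(k(B+1))`, so B = 100 suffices for a 32-taxon network but small families
need more replicates.  The default edge rule keeps `|rho| > 0.7` and
`q < 0.05`, retaining the sign as an edge attribute; a strict signed mode
(`rho > 0.7` only) is available because descriptions of such filters are
often ambiguous about the sign.

## Modules and per-sample topology

Module detection is agglomerative greedy modularity maximisation on the
unweighted, unsigned graph: starting from singletons, repeatedly merge the
connected pair of communities with the largest gain
`e_ab/m - d_a d_b/(2 m^2)`, tracking the best Newman–Girvan Q along the
merge path.  Ties on the gain are broken by the lexicographically smallest
pair of community representatives (a community is named by its smallest
member), which makes the procedure fully deterministic and invariant to node
input order — a property the tests assert.  Isolated nodes stay singletons.
Modules holding strictly more than 10% of the network's nodes are labelled
M1, M2, ... by descending size.  Q is computed on the unweighted graph;
signed or weighted modularity variants are out of scope.

Per-sample statistics are computed on the subgraph induced by the taxa with
strictly positive relative abundance in that sample: mean degree `2E/N`,
linkage density `2E/N^2` (mean degree over nodes), modularity of a fresh
module detection on the subnetwork (re-detection, rather than restricting
the global partition, treats each sample as its own ecosystem; the global
partition is available separately), and the mean max-normalised eigenvector
centrality.  Centrality uses power iteration on `A + I` — the identity
shift separates the leading eigenvalue on bipartite components where plain
power iteration oscillates — restricted to the largest connected component
(nodes outside it score 0), and matches a dense eigendecomposition to 1e-8
on all tested graphs.  Subnetworks with fewer than two nodes are degenerate;
they report zeros plus a flag so downstream feature tables stay rectangular.
Because a per-sample scalar is needed for association analyses, "degree" is
reported as the mean degree and "centrality" as the mean eigenvector
centrality; these are definitional choices, as is presence = abundance > 0
(no detection floor is assumed).

## Diversity, group tests and trends

Shannon entropy (natural log), Bray–Curtis dissimilarity and PERMANOVA are
delegated to vegan; beta-diversity group comparisons use within-group
pairwise distances compared across groups by Kruskal–Wallis (within-group
rather than all-pairs distances, so a location shift between groups does not
masquerade as a dispersion difference).  The PERMANOVA wrapper seeds its
permutations explicitly and exposes sequential (type-I-like) two-factor
decomposition so the variance explained by, say, treatment vs antibiotic use
can be compared in a stated order.  The abundance screen applies
tie-corrected Kruskal–Wallis tests to the top-k most abundant features and
retains p < 0.05 *unadjusted* by default — mirroring the common screening
procedure — with a BH-adjusted mode available.

Time trends are fitted by least squares as a quadratic in integer group rank
(R00 = 0 ... R05 = 5).  The quadratic is the minimal family expressing both
U-shaped and inverse-U trajectories over six ordered timepoints; encoding
time as rank rather than calendar days avoids the half-year timepoint
dominating the leverage of the fit.  A fit is *convex* when the quadratic
coefficient is positive (numerically-zero coefficients are truncated so
constant data are not classified convex) and *U-shaped* when additionally
the vertex falls inside the observed rank range.

## Clinical associations

eGFR uses the CKD-EPI piecewise power law; the 2021 race-free refit is the
default (the 2009 equation, with optional race coefficient, is provided).
Creatinine must carry an explicit unit — µmol/L is converted to mg/dL by
1/88.42 and unit-less input is refused, because published tables sometimes
misprint the unit and a silent guess would be off by two orders of
magnitude.  The equation is continuous at the creatinine knot and monotone
decreasing, both asserted numerically.

Associations between network features (module abundances, modularity,
linkage density/complexity, centrality, degree) and clinical indicators use
tie-corrected Spearman correlation with pairwise-complete missing-value
handling and significance stars at 0.05/0.01/0.001; constant margins are
reported as missing with a flag.

The random-forest stage regresses eGFR on the feature table: `mtry` is tuned
by 10-fold cross-validation (folds disjoint, exhaustive, balanced within
one) minimising RMSE; the final forest reports permutation importance as the
raw mean increase in out-of-bag MSE.  Significance comes from
response-permutation replicates: permuting the response severs every
feature–response link while preserving the response's marginal, and each
refit contributes one draw to both the per-feature importance null and the
model-level out-of-bag R² null, with add-one p-values.  Defaults are 500
trees and 100 permutation replicates; the property simulations in the test
suite use 300 trees and 20–99 replicates at n = 80–100 with 8–10 features,
which keeps the full suite within a desk-scale compute budget while leaving
the recovery and calibration margins wide.

## Problem sizes used by the tests and acceptance script

Recovery and calibration claims are computed at: null calibration, 20 seeds
of 30 independent taxa × 200 samples; parameter recovery, 20 seeds of two
8-taxon 0.8-blocks among 30 taxa × 500 samples (median RMSE ≈ 0.04);
module recovery, 20 seeds of four 8-taxon blocks × 500 samples (median
adjusted Rand index 1.0 in our runs); PERMANOVA calibration, 400–1000 null
simulations of 15 + 15 samples × 20 taxa at 199 permutations (type-I ≈
0.042–0.05); Kruskal–Wallis calibration and power, 50 seeds × 50 features;
random-forest recovery and null, 20 and 40 seeds.  Monte Carlo sizes were
chosen so that each rate's sampling error is small against the margin being
asserted; with very small batches a calibrated procedure still fails its
nominal band a few percent of the time, which is noise, not miscalibration.

## Known limitations

* SparCC's sparsity assumption: estimates degrade as the fraction of truly
  correlated pairs grows; the pathological two-block-no-background case is
  documented above.
* Under planted independence the estimated correlations fluctuate like
  empirical correlations (sd ≈ 1/sqrt(n)); with hundreds of pairs the
  maximum |rho| at n = 200 is typically 0.2–0.3, so hard thresholds well
  below that are only meaningful at larger n.
* Zero handling is pseudocount-based; tables dominated by structural zeros
  deserve a dedicated zero model.
* Modularity is unweighted and unsigned; negative edges contribute topology
  but not repulsion.
* The clinical simulator couples indicators linearly; it validates sign and
  rank recovery, not effect-size estimation under realistic confounding.
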