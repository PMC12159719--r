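---
title: "Environment ensembles for genomic prediction in sparse METs"
author: "metEnsembleGP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Environment ensembles for genomic prediction in sparse METs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Cooperative nursery trials evaluate a shared panel of genotypes at many
locations over many years, but sparsely: a typical entry is grown at only a
subset of locations, for a couple of consecutive years. A breeder at one
location wants genomic predictions for that location. The question this
package addresses is how to use the *other* locations' data: pool
everything into one training set (the **singular** approach), train one
submodel per location and average their predictions (the **environment
ensemble**), or keep only the subset of location submodels that provably
help on a validation set (the **optimized ensemble**). Each regime can sit
on top of three base learners: ordinary least squares, ridge regression,
and a feed-forward neural network.

## Data model and the synthetic generator

All estimators assume the decomposition that the generator implements
forwards. Within a location, the phenotype of genotype *i* in year *k* is

    Y_ik = mu + G_i + S_k + e_ik

with genotype fixed, year random, and independent Gaussian residuals.
Across locations, genetic values are driven by additive marker effects that
mix a component shared by all locations (weight sqrt(rho)) with a
location-specific component (weight sqrt(1 - rho)); the mixture is rescaled
so the genotypic standard deviation at location *l* equals its
**discriminativeness** d_l. Genotype dosages are Hardy-Weinberg draws of
unlinked markers with minor-allele frequencies sampled uniformly from a
configurable range.

The generator's defaults emulate a sparse cooperative bean nursery: 300
genotypes, ~1,100 retained SNPs, 18 locations, each genotype grown at a
subset of locations for two consecutive years. Discriminativeness spans
0.2x-5x geometrically across locations and the per-location heritability
target follows `h2 = d^2 / (d^2 + 1 + sd_year^2)`, i.e. a constant unit
residual variance at every location. Two observations motivate that
coupling: field residual noise is of similar magnitude across sites, while
discriminating sites are the ones with more genotypic variance; and the
implied heritability ladder (~0.04-0.96) matches the spread reported for
real per-location nursery heritabilities.

Residual variance is back-solved from the heritability target via
`sigma_e^2 = sigma_g^2 (1 - H^2) / H^2 - sigma_year^2` so that the
*expected* within-location broad-sense heritability equals the target. A
target of exactly 0 with genetic signal present, or of exactly 1 with year
effects present, is rejected; a year variance exceeding the implied
non-genetic variance floors the residual variance at 1e-8 with a warning.
Every draw is recorded in a truth channel (`GroundTruth`), including the
per-record decomposition, so parameter-recovery tests can check the
pipeline against exact known values.

What the generator does **not** emulate: linkage disequilibrium, population
structure and pedigrees, dominance or epistasis, multi-trait correlations,
and location-pair-specific genetic correlations (the between-location
correlation is a single rho for all pairs). Tests that pass on this
generator therefore validate the estimators' statistical logic, not their
behavior under structured LD panels.

## BLUEs and heritability

Genotype means per location are estimated from two companion REML fits
(`lme4`): genotype *fixed* plus year *random* for the BLUEs (reported as
adjusted means on the grand-mean-plus-genotype-effect scale, so they are
comparable across genotypes within a location), and genotype *random* plus
year random for the variance components. The second fit exists because a
fixed effect has no variance component; treating genotype as random for
`sigma_g^2` while using the fixed-genotype fit for the means is the
standard resolution, and both fits are run on the same records.
Broad-sense heritability is `H2 = sigma_g2 / (sigma_g2 + sigma_i2 +
sigma_e2)`, where `sigma_i2` is the within-location year variance.

Degenerate slices are handled explicitly: a single-year location fixes
`sigma_i2 = 0`; a single *unreplicated* year confounds genotypic and
residual variance, in which case the sample variance is attributed to
genotypes with a warning. REML estimates at the zero boundary are reported
as 0 (lme4 never returns negative components).

## Base learners

**OLS and ridge** are computed from the SVD of the column-centered feature
matrix: the intercept is unpenalized, `lambda = 0` yields the minimum-norm
solution on rank-deficient systems, and `lambda > 0` yields the exact
closed-form ridge solution. The SVD route was chosen over an iterative
solver because the tests assert agreement with closed forms at 1e-8, and
because minimum-norm behavior for p > n blocks is load-bearing (single
locations routinely have fewer genotypes than selected markers). The ridge
penalty is selected per training set by 3-fold cross-validation over the
log grid {0.01, 0.1, 1, 10, 100, 1000}, scored by held-out Pearson
correlation; ties keep the smallest penalty.

**The network** is fully connected with ReLU hidden layers, a linear
output, MSE loss and Adam (beta1 = 0.9, beta2 = 0.999, eps = 1e-8),
scaled-uniform fan-in initialization under the run seed, and inputs
standardized with training-block statistics. Hyperparameters are drawn by
random search from: learning rate log10-uniform on [-4, 2]; batch size 2^k,
k uniform on {2..7}; 3-8 hidden layers; layer width 3-100 (one width for
all hidden layers, read off the single sampled number). Training stops when
the loss tail is convex — consecutive decrements shrinking over a 3-epoch
window, the smallest window that defines curvature — *and* the last
relative decrease is below 5%, or at 50 epochs. The full search uses 300
draws with 3-fold CV; pipeline defaults use 30 (and the test suite fewer),
a scale chosen for interactive runs — the search size is a parameter, not a
different algorithm.

## Ensembles and their optimization

Ensemble prediction is always the unweighted arithmetic mean of submodel
predictions. For linear bases the environment ensemble trains one submodel
per training location. For networks, single locations are usually too small
to train a network, so ensembles are **bagged** over environments: each
submodel trains on L location blocks drawn with replacement from the L
training locations. The bag count defaults to 5 and can be tuned over
{3, 5, 7, 10, 15} by validation accuracy (`tuneBagSize`).

Optimization is greedy single-dropout: score the full ensemble on a
validation set (Pearson r), drop each submodel in turn *from the full
ensemble*, and exclude it iff the dropout score strictly beats the
baseline. Ties conservatively keep the location. If everything would be
excluded, the single most valuable submodel is retained with a warning.
Judging each candidate against the full ensemble (rather than a
sequentially shrinking one) is the most literal reading of leaving
locations out "one by one"; on adversarial constructions the greedy result
provably coincides with exhaustive best-subset search, which the tests
verify for up to 8 submodels.

The validation set is a genuinely open choice. The default carves a 20%
genotype-stratified holdout out of the training locations' rows: submodels
are refit without the held genotypes, dropout decisions are made on them,
and the surviving locations' full-data submodels form the final ensemble.
A `validationMode = "leaky"` switch instead scores candidates
directly on the test location, replicating a protocol in which the test
set itself guides pruning; it is provided for comparison and labelled
leaky because it inflates optimized-ensemble accuracy.

## Cross-validation and the threshold statistic

Evaluation is leave-one-location-out: each location in turn is the test
set, everything else trains. Accuracy is the Pearson correlation between
predicted and observed BLUEs at the test location; undefined correlations
(constant vectors) are recorded as missing rather than zero so they cannot
bias averages. Per-fold seeds are derived from the location *name*, making
every fold's result independent of location ordering, and one derived seed
feeds all stochastic components of a fold.

The variance-threshold statistic summarizes where ensembling pays off:
per trait x base, locations are sorted by phenotypic variance (sample
variance of the location's BLUEs) and the threshold is the largest variance
v* such that the ensemble beats the singular model at *every* location with
variance at or below v*; the statistic is v* / max(variance) x 100,
averaged over combinations. This walk-from-the-bottom operationalization is
one of several defensible readings of a "variance threshold below which the
ensemble is ideal"; the per-combination values are emitted so alternatives
can be recomputed.

## The discriminativeness contrast study

`ensembleContrastStudy()` packages the experiment behind the package's
central qualitative claim: ensembling helps at low-discriminativeness test
locations and not at high ones. Its design places the data where the
bias-variance gap between pooling and averaging is actually expressed:
6 locations spanning 0.2x-5x discriminativeness with constant unit residual
noise (so heritability spans ~0.04-0.96), 60 genotypes grown at ~3.2
locations each, and 30 PCA-selected markers — per-location blocks of ~32
rows, comparable to the feature count, the regime where single-location
least squares is variance-dominated. When the most discriminating location
is *in* the training set (i.e. when testing the least discriminating one),
its large-variance block destabilizes the pooled fit and averaging wins;
when it is held out for testing, pooling the remaining, more homogeneous
blocks wins. Pilot-style exploration shows the high-discriminativeness side
of the contrast is strong and stable, while the low-side advantage is small
relative to 20-seed Monte-Carlo noise; the packaged study reports per-seed
differences so users can judge the margin themselves.

## Numerical choices

- PCA feature selection mean-centers dosage columns without unit-variance
  scaling (preserving allele-frequency-driven variance weighting), ranks
  components by eigenvalue, and maps each component to the SNP with the
  largest absolute loading not yet selected, walking down the component's
  ranking on collision. Absolute loadings are quantized at 1e-9 before
  ranking so algebraically tied loadings (duplicated columns) break
  lexicographically by SNP id rather than by floating-point noise; the
  selection is then invariant to column order. Components are well defined
  only up to the matrix rank; requesting more components than
  min(genotypes, SNPs) is an error, and the default is the observation
  limit min(n - 1, p).
- The GGE analysis fills missing genotype x environment cells with the
  environment's observed mean (zero after centering) and reports the fill
  fraction, making heavy sparsity visible. SVD sign ambiguity is fixed per
  component so the largest-magnitude environment loading is positive.
  Vector lengths use the first two components; pairwise cosines use all
  components, so environment-score inner products equal the centered
  cross-products exactly and cosines approximate between-environment
  correlations even when two components truncate badly.
- MAF filtering keeps columns with minor-allele frequency *strictly* above
  the threshold, with frequency computed from mean dosage; the filter is
  idempotent.
- Tabular outputs are written with full double precision (`%.17g` for
  phenotypes), so a run re-ingested from its own files reproduces the
  original results bit for bit.

## Problem sizes

The test suite and the reproduction script run everything at desk scale,
chosen as the smallest sizes at which each statistical property is
comfortably expressed: heritability recovery uses 200 genotypes x 5 years
x 20 seeds; the accuracy-vs-heritability contrast uses 80 genotypes, 4
complete locations, 10 seeds per heritability level; the contrast study
uses the design above with 20 seeds; the end-to-end run uses 120 genotypes,
300 markers, 10 locations. The full-scale defaults (300 x 1,100 x 18)
remain the generator's defaults and run in minutes rather than seconds.

## Known limitations

- The optimized ensemble's holdout validation removes 20% of genotypes
  from submodel training during the dropout decisions; with very small
  location blocks the decisions become noisy, and the leaky mode is
  then the only stable (if optimistic) alternative.
- Variance components at the REML boundary are reported as 0 rather than
  flagged; heritabilities of exactly 0 or 1 in the output usually indicate
  a boundary fit, not a precise estimate.
- The network learner is a plain dense ReLU network trained on CPU; it is
  faithful to the tuning/stopping protocol but not optimized for panels
  with tens of thousands of markers.
- Accuracy is Pearson correlation throughout; rank-based or slope-aware
  metrics (bias of predictions) are out of scope.
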