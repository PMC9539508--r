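---
title: "Modelling growth-rate drivers in mixed-species plantings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling growth-rate drivers in mixed-species plantings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revegrowth)
```

## The scientific problem

Revegetation plantings mix many woody species, and which species thrive
where is only partly predicted by commonly measured functional traits.
This package implements an analysis of *individual relative growth rate*
(RGR) for focal Acacia and Eucalyptus plants in such plantings, asking
whether trait, climate and neighborhood correlates of growth differ by
genus and shift along a moisture-availability gradient.

The response for each focal plant is

\[ \mathrm{RGR} = \frac{\ln B}{t}, \]

with \(B\) the aboveground biomass in kg estimated from stem diameter via
an allometric equation \(\ln B = a + b \ln D\), and \(t\) the planting age
in years. This assumes plants started from negligible mass at planting;
plants below 0.1 kg are excluded as likely post-planting recruits (they
stay in the data as neighbors). The natural logarithm is used throughout —
any other base would rescale all slopes by a common constant.

## Predictors

Each focal's plot neighborhood (all plants in the plot minus the focal,
any genus) yields five metrics:

* **Neighbor density**: \((n-1)\) plants divided by plot area in hectares.
* **Conspecific proportion**: conspecific neighbors over all neighbors.
* **Rarefied richness**: expected species count in a subsample of
  \(n = 9\) individuals, \(E[S_n] = \sum_i \left(1 -
  \binom{N-N_i}{n}\big/\binom{N}{n}\right)\), computed with log-space
  binomial coefficients. Nine reflects a design floor of ten plants per
  plot, minus the focal; plots with fewer neighbors get a missing value
  and drop out of models that use richness.
* **Functional evenness (FEve)** and **functional dispersion (FDis)** on
  the three species-mean traits (SLA, wood density, maximum height),
  z-standardized over the dataset's full species pool and compared by
  Euclidean distance. FEve measures the regularity of abundance-weighted
  spacing along the minimum spanning tree of trait space; FDis the
  abundance-weighted mean distance to the abundance-weighted centroid.
  Species missing any trait are dropped from these two indices with
  abundances renormalized, and logged per plot. Functional range is
  computed for reports but never modelled: it is nearly collinear with
  richness.

Minimum spanning trees are built with Prim's algorithm with deterministic
tie-breaking by (distance, species index); since traits are continuous,
ties have probability zero and the MST is almost surely unique, which is
why an independent Kruskal implementation must agree to 1e-10 in the test
suite.

Missing traits of non-focal species are interpolated as the mean of
congeners' species means from plots within 50 km (haversine distance) of
any plot containing the species; species with no measured congener in
radius stay missing and are reported. Whether one should average congener
species means or the underlying individual measurements is ambiguous;
this package averages species means, the only quantity it has.

## Transformations, standardization, collinearity

Planting age, maximum height and solar radiation are log-transformed and
neighbor density square-root transformed before modelling (always
transform first, then standardize). All continuous predictors are then
z-scored using the sample (n−1) standard deviation with both genera
pooled, so genus-specific partial slopes are directly comparable; the
centers and scales are stored so raw moisture values (e.g. 0.27) can be
mapped to the model scale later. Variance inflation factors are screened
against a threshold of 3 before fitting.

## The seven-model ladder

All models share four random intercepts — plots within plantings within
subregions, crossed with species — and are fit with `lme4`: REML for
reported estimates, ML refits for AIC and likelihood-ratio comparison
(AIC counts fixed effects plus variance components including the
residual). The fixed-effect structure grows in seven steps: intercept
only (*base*); all continuous predictors (*no genus*); plus a genus main
effect (*genus intercepts*); plus genus × predictor interactions (*genus
slopes*); and the three *moisture* variants adding moisture × predictor
two-way terms or the full genus × moisture × predictor three-way terms.
Marginality is enforced: every interaction's lower-order terms are
included, and the plot-area × conspecific-proportion interaction (the one
plot-area interaction retained by the screening step implemented in
`plotAreaScreen()`) appears in every model that has the conspecific
proportion. Genus uses treatment contrasts with Acacia as reference, but
per-genus slopes are always reported as linear combinations (Acacia:
\(\beta_p\); Eucalyptus: \(\beta_p + \beta_{p\times genus}\)) with
delta-method standard errors, which makes the output invariant to the
coding.

Pseudo-R² follows the variance-partition definition for Gaussian mixed
models: with \(\sigma^2_f\) the population variance of the fixed-effect
predictions, marginal \(= \sigma^2_f / (\sigma^2_f + \sum_l \sigma^2_l +
\sigma^2_e)\) and conditional adds the summed random-intercept variances
to the numerator. Boundary variance estimates are reported as zero;
likelihood-ratio p-values are plain upper-tail chi-square without
boundary correction.

## Permutation nulls for partial slopes

Null distributions for standardized partial slopes are built by shuffling
growth rates across *all* focal plants (unrestricted, not stratified;
a stratified variant can be composed from `permuteGrowth` on subsets) and
refitting the full model — random effects re-estimated each time — 1000
times by default (tests and examples use fewer). For the moisture model,
genus-specific slopes are evaluated at *dry* and *mesic* conditions: the
10th and 90th moisture quantiles of the dataset by default, or fixed raw
values such as 0.27 and 0.76 on request. Empirical p-values are two-sided
with the add-one correction, \(p = (1 + \#\{|s^\ast| \ge |s|\}) /
(n_{perm} + 1)\), never exactly zero. Per-permutation seeds are
`base_seed + i`, so the null set is reproducible and trivially
parallelizable.

**A calibration caveat.** A permutation test is exact only when the
response is exchangeable under the null. Shuffling growth rates destroys
not only predictor–growth association but also the planting/plot/species
correlation structure, so for predictors that vary at cluster level
(traits, climate, density) the null slope distribution is narrower than
the sampling distribution of the observed slope whenever cluster-level
variance is present — the unrestricted shuffle is then anticonservative.
The package's calibration tests therefore simulate data that satisfy the
permutation null (no fixed effects, no cluster variance): there the
null-exclusion test holds its nominal 5% level and the null spread tracks
the model-based slope standard error. On data with realistic variance
components, rejection rates for cluster-level coefficients run far above
nominal; conclusions drawn from these nulls inherit that property of the
method.

## The synthetic-data generator

No raw planting inventory is public, so the generator emulates the
sampling design the analysis assumes, with known ground truth:

* ~137 plantings over 12 biogeographic subregions; plots per planting
  from a truncated negative binomial whose *post-truncation* mean is 3.63
  (sd 3.99 before truncation), giving ≈500 plots; 34.8 plants per plot
  (sd 25.6, minimum 2).
* planting ages truncated-normal on [4, 33] yr with mean 12 and sd 5.3;
  square plot areas truncated-normal below 400 m².
* moisture availability uniform on (0.209, 0.821), chosen so the 10th and
  90th dataset quantiles land near the conventional dry/mesic evaluation
  values 0.27 and 0.76; solar radiation is a Gaussian linear response to
  moisture calibrated to a correlation of −0.69.
* per-genus log-normal species-mean trait distributions that overlap
  broadly between Acacia and Eucalyptus (Eucalyptus taller); a pool of
  "Other" neighbor species with ~45% missing traits exercises congener
  interpolation.
* plot composition from planting-level species palettes with
  Dirichlet(0.8)-multinomial abundances, so conspecific proportion
  varies; stem diameters log-normal with age-dependent location so
  biomass spans the 0.1 kg exclusion boundary; 5% of plants carry a
  second stem (mallee forms), testing per-plant stem summing.
* growth simulated as \(X\beta\) on the standardized scale plus one
  intercept draw per subregion/planting/plot/species plus residual noise;
  realized intercepts are stored for recovery tests.

Default truth coefficients (`defaultTruth()`) give main effects of
standardized magnitude 0.01–0.08 with the signs expected for the system
(slower growth with age, density and conspecific crowding; faster with
SLA and neighborhood diversity) and set every genus/moisture interaction
to magnitude 0.05. Variance components (subregion 0.010, planting 0.030,
plot 0.020, species 0.040, residual 0.135) were chosen so fixed effects
explain roughly a fifth and random intercepts roughly a third of
growth-rate variance, the partition typical of growth models of this
kind. A single master seed fans out to fixed per-stage child seeds, so
each generation stage is independently reproducible.

What the generator does *not* emulate: stem coordinates within plots (no
distance-weighted neighborhoods), survival or mortality, grass-layer
competition, intraspecific trait variation, or spatially autocorrelated
climate. Passing tests therefore demonstrate that the pipeline recovers
known structure under its own assumptions, not that those assumptions
hold in any particular field dataset.

## Numerical choices and problem sizes

* `lme4` fits use `calc.derivs = FALSE`; singular (boundary) fits are
  accepted and flagged rather than errored, since truth sets with zero
  variances are a deliberate test case.
* The likelihood is exactly invariant to row permutation, but optimizer
  stopping rules are not: estimates from row-shuffled data agree to about
  1e-4 (relative), and the test suite asserts exactly that.
* Degenerate inputs: empty neighborhoods give missing conspecific
  proportion; fewer than 3 trait-complete species give missing FEve;
  coincident trait points give zero MST edge lengths (FEve undefined,
  returned missing); a constant predictor column is an error at
  standardization.
* Test-suite problem sizes are chosen for a single desktop CPU: parameter
  recovery uses 20 replicate datasets of ~120 plantings (~8,000 focals);
  ladder discrimination 25 such replicates; null calibration 30 datasets
  of ~2,500 focals with 199 permutations each, pooling 8 slope statistics
  per dataset; coverage of fixed effects is assessed pooled over
  coefficient × replicate pairs.

## A worked example

```{r example, eval = FALSE}
cfg <- simConfig(n_plantings = 40, seed = 1)
sim <- simulateDataset(cfg)                  # truth = defaultTruth()
fits_ml <- fitLadder(sim$analysis, method = "ML")
fits_reml <- fitLadder(sim$analysis, method = "REML")
comparisonTable(fits_ml, fits_reml)

nulls <- nullSlopeDistributions(sim$analysis,
                                modelLadder()$genus_slopes_moisture,
                                n_perm = 199, base_seed = 42,
                                observed_fit = fits_reml$genus_slopes_moisture)
head(compareAndReport(nulls))
```

## Known limitations

* The permutation null is anticonservative for cluster-level predictors
  under cluster-structured noise (above); a stratified shuffle would
  trade that for a different, narrower null hypothesis.
* Species-mean traits ignore intraspecific variation; the species random
  intercept absorbs some, but trait-slope estimates remain attenuated
  relative to an individual-trait analysis.
* AIC parameter counts treat variance components as ordinary parameters;
  boundary cases mean the chi-square reference for LRTs involving
  variances would be conservative (only fixed-effect comparisons are made
  here).
* The allometry shipped with the package is synthetic; real analyses must
  supply a validated coefficient table via `readAllometry()`.
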