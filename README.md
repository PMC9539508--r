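# revegrowth

Drivers of individual plant growth in mixed-species restoration
plantings: an R package for ecologists modelling how functional traits,
climate and neighborhood structure correlate with the relative growth
rate of woody plants — and whether those correlations differ between
co-occurring genera (Acacia vs Eucalyptus) and shift along a
moisture-availability gradient.

## What it computes

For each focal plant, relative growth rate is

    RGR = ln(B) / t        [kg kg⁻¹ yr⁻¹]

with aboveground biomass `B` (kg) from a diameter-based allometric
equation `ln B = a + b ln D` and `t` the planting age (yr). Focal plants
below 0.1 kg are excluded (likely post-planting recruits); every plant
remains a neighbor. Per-focal neighborhood predictors are computed from
all plants in the plot minus the focal: density (plants ha⁻¹),
conspecific proportion, rarefied species richness
`E[Sₙ] = Σᵢ (1 − C(N−Nᵢ, n)/C(N, n))` at n = 9, and the functional
diversity indices FEve (minimum-spanning-tree evenness) and FDis
(abundance-weighted centroid dispersion) on z-standardized species-mean
traits (SLA, wood density, maximum height).

Growth is modelled with linear mixed models (lme4) carrying four crossed
random intercepts — plot within planting within subregion, crossed with
species — through a ladder of seven fixed-effect structures, from an
intercept-only base model up to genus × moisture × predictor three-way
interactions. Models are compared by AIC and likelihood-ratio tests on
ML refits, with marginal/conditional pseudo-R². Standardized partial
slopes per genus (evaluated at dry and mesic moisture conditions for the
moisture model) are tested against permutation null distributions built
by shuffling growth rates across all focal plants and refitting.

Because raw planting inventories of this kind are typically held under
data-sharing agreements, the package includes a first-class synthetic
data generator (`simConfig()`, `simulateDataset()`) that emulates the
nested sampling design — ~137 plantings, ~500 plots, tens of thousands
of plants, overlapping genus trait distributions, a moisture gradient
with correlated solar radiation — under a known ground-truth coefficient
set, so the entire pipeline is testable end to end.

## A worked example

```r
library(revegrowth)

cfg <- simConfig(n_plantings = 40, seed = 1)
sim <- simulateDataset(cfg)        # ground truth = defaultTruth()
sim
#> <revegSim> 40 plantings / 150 plots / 2513 focals in the analysis table; 266 small focals excluded

fits_ml   <- fitLadder(sim$analysis, method = "ML")
fits_reml <- fitLadder(sim$analysis, method = "REML")
comparisonTable(fits_ml, fits_reml)[, c(1, 2, 3, 6, 7)]
#>                       model      AIC dAIC_base marginal_r2 conditional_r2
#> 1                      base 2651.525     0.000       0.000          0.571
#> 2                  no_genus 2610.746   -40.779       0.207          0.583
#> 3          genus_intercepts 2611.448   -40.078       0.212          0.585
#> 4              genus_slopes 2584.300   -67.225       0.232          0.582
#> 5         no_genus_moisture 2586.794   -64.731       0.247          0.605
#> 6 genus_intercepts_moisture 2586.970   -64.556       0.255          0.607
#> 7     genus_slopes_moisture 2524.130  -127.396       0.296          0.597
```

The generating model (`genus_slopes_moisture`) has the lowest AIC; its
fixed effects explain ~30% of growth-rate variance and fixed plus random
effects ~60%, close to the generating shares. Genus-specific slopes
versus their permutation nulls:

```r
nulls <- nullSlopeDistributions(sim$analysis,
                                modelLadder()$genus_slopes_moisture,
                                n_perm = 199, base_seed = 42,
                                observed_fit = fits_reml$genus_slopes_moisture)
subset(compareAndReport(nulls), predictor == "density")
#>    predictor      genus condition observed    se null_lo null_hi null_sd     p        flag
#> 29   density     Acacia       dry   -0.105 0.068  -0.119   0.114   0.057 0.095          ns
#> 30   density     Acacia     mesic    0.112 0.067  -0.086   0.090   0.048 0.025 significant
#> 31   density Eucalyptus       dry   -0.114 0.054  -0.065   0.060   0.034 0.005 significant
#> 32   density Eucalyptus     mesic    0.016 0.062  -0.082   0.078   0.042 0.650          ns
```

(Values rounded to 3 digits.) Each row is a genus-specific partial
slope of neighbor density at a moisture condition (dataset 10th/90th
quantiles), its delta-method SE, the null 95% interval from 199
growth-shuffles, and the add-one empirical p — the machine-readable
analogue of slope-versus-null figures. `runPipeline()` wires all stages
together and writes every table as CSV;
`inst/cli/revegrowth.R run --seed 1 --out dir` is a thin command-line
wrapper around it.

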