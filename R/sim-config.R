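#' Configuration for the synthetic planting-data generator
#'
#' Collects every knob of the synthetic sampling design in one validated
#' object. Defaults emulate a continental network of mixed-species
#' revegetation plantings surveyed with square neighborhood plots: 137
#' plantings spread over biogeographic subregions, a mean of ~3.6 plots per
#' planting, plots holding on average ~35 woody plants (heavily
#' overdispersed), planting ages averaging 12 yr on a 4--33 yr range, plot
#' areas below 400 m-squared, and a moisture-availability gradient (annual
#' rainfall / annual potential evapotranspiration) whose 10th and 90th
#' quantiles fall near 0.27 and 0.76. Solar radiation is generated with a
#' configurable (negative, by default -0.69) correlation to moisture.
#'
#' Two focal genera, Acacia and Eucalyptus, receive overlapping log-normal
#' species-mean trait distributions (SLA in mm^2/g, wood density in g/cm^3,
#' maximum height in m); an additional pool of non-focal "Other" species has
#' partially missing traits so that congener interpolation has work to do.
#'
#' @param n_subregions Number of biogeographic subregions.
#' @param n_plantings Number of plantings (sites).
#' @param plots_per_planting_mean,plots_per_planting_sd Mean/sd of the
#'   per-planting plot count (truncated negative binomial, minimum 1).
#' @param plants_per_plot_mean,plants_per_plot_sd Mean/sd of the per-plot
#'   woody plant count (truncated negative binomial, minimum 2).
#' @param species_per_plot_mean,species_per_plot_sd Mean/sd of the number of
#'   species present in a plot.
#' @param n_species_acacia,n_species_eucalyptus,n_species_other Species pool
#'   sizes per genus ("Other" species are neighbors only, never focal).
#' @param other_trait_missing Probability that a given trait of an "Other"
#'   species is unmeasured (exercises congener interpolation).
#' @param age_mean,age_sd,age_min,age_max Planting age distribution (yr):
#'   normal truncated to `[age_min, age_max]`.
#' @param plot_area_mean,plot_area_sd,plot_area_min,plot_area_max Plot area
#'   distribution (m^2): normal truncated to `[plot_area_min, plot_area_max)`.
#' @param moisture_range Length-2 interval for the uniform moisture
#'   availability ratio; must lie inside (0, 2).
#' @param radiation_mean,radiation_sd Marginal mean/sd of annual-mean solar
#'   radiation (MJ m^-2 day^-1).
#' @param radiation_moisture_corr Target Pearson correlation between
#'   planting-level moisture and solar radiation; strictly inside (-1, 1).
#' @param trait_distributions Named list (Acacia, Eucalyptus, Other), each a
#'   list with elements `sla`, `wood_density`, `max_height`, each c(meanlog,
#'   sdlog) of a log-normal.
#' @param lon_range,lat_range Geographic window for planting coordinates
#'   (decimal degrees); only used for congener-interpolation distances.
#' @param prop_multi_stem Fraction of plants carrying a second stem row.
#' @param seed Integer master seed; stage-level child seeds are derived from
#'   it by fixed offsets so each generation stage is independently
#'   reproducible.
#' @return An object of class `simConfig` (a validated named list).
#' @seealso [generateSpeciesPool()], [generateLandscape()], [simulateDataset()]
#' @export
simConfig <- function(n_subregions = 12,
                      n_plantings = 137,
                      plots_per_planting_mean = 3.63,
                      plots_per_planting_sd = 3.99,
                      plants_per_plot_mean = 34.81,
                      plants_per_plot_sd = 25.61,
                      species_per_plot_mean = 4.0,
                      species_per_plot_sd = 1.84,
                      n_species_acacia = 43,
                      n_species_eucalyptus = 80,
                      n_species_other = 30,
                      other_trait_missing = 0.45,
                      age_mean = 12, age_sd = 5.27,
                      age_min = 4, age_max = 33,
                      plot_area_mean = 231.84, plot_area_sd = 115.68,
                      plot_area_min = 25, plot_area_max = 400,
                      moisture_range = c(0.209, 0.821),
                      radiation_mean = 18, radiation_sd = 2.2,
                      radiation_moisture_corr = -0.69,
                      trait_distributions = defaultTraitDistributions(),
                      lon_range = c(116, 152), lat_range = c(-38, -27),
                      prop_multi_stem = 0.05,
                      seed = 1L) {
  cfg <- list(
    n_subregions = as.integer(n_subregions),
    n_plantings = as.integer(n_plantings),
    plots_per_planting_mean = plots_per_planting_mean,
    plots_per_planting_sd = plots_per_planting_sd,
    plants_per_plot_mean = plants_per_plot_mean,
    plants_per_plot_sd = plants_per_plot_sd,
    species_per_plot_mean = species_per_plot_mean,
    species_per_plot_sd = species_per_plot_sd,
    n_species_acacia = as.integer(n_species_acacia),
    n_species_eucalyptus = as.integer(n_species_eucalyptus),
    n_species_other = as.integer(n_species_other),
    other_trait_missing = other_trait_missing,
    age_mean = age_mean, age_sd = age_sd,
    age_min = age_min, age_max = age_max,
    plot_area_mean = plot_area_mean, plot_area_sd = plot_area_sd,
    plot_area_min = plot_area_min, plot_area_max = plot_area_max,
    moisture_range = as.numeric(moisture_range),
    radiation_mean = radiation_mean, radiation_sd = radiation_sd,
    radiation_moisture_corr = radiation_moisture_corr,
    trait_distributions = trait_distributions,
    lon_range = as.numeric(lon_range), lat_range = as.numeric(lat_range),
    prop_multi_stem = prop_multi_stem,
    seed = as.integer(seed))
  class(cfg) <- "simConfig"
  validateSimConfig(cfg)
  cfg
}

#' @export
print.simConfig <- function(x, ...) {
  cat("<simConfig>\n")
  cat(sprintf("  %d plantings in %d subregions; ~%.1f plots/planting; ~%.1f plants/plot\n",
              x$n_plantings, x$n_subregions,
              x$plots_per_planting_mean, x$plants_per_plot_mean))
  cat(sprintf("  species pool: %d Acacia, %d Eucalyptus, %d other\n",
              x$n_species_acacia, x$n_species_eucalyptus, x$n_species_other))
  cat(sprintf("  ages %g-%g yr; moisture %.3f-%.3f; cor(radiation, moisture) = %.2f; seed %d\n",
              x$age_min, x$age_max, x$moisture_range[1], x$moisture_range[2],
              x$radiation_moisture_corr, x$seed))
  invisible(x)
}

validateSimConfig <- function(cfg) {
  stopifnot(inherits(cfg, "simConfig"))
  counts <- c(cfg$n_subregions, cfg$n_plantings, cfg$n_species_acacia,
              cfg$n_species_eucalyptus)
  if (any(counts < 1))
    stop("simConfig: subregion, planting and focal species counts must be positive",
         call. = FALSE)
  if (cfg$n_species_other < 0)
    stop("simConfig: n_species_other must be non-negative", call. = FALSE)
  if (cfg$plots_per_planting_mean <= 0 || cfg$plants_per_plot_mean < 2)
    stop("simConfig: infeasible plot/plant counts", call. = FALSE)
  if (length(cfg$moisture_range) != 2L ||
      cfg$moisture_range[1] <= 0 || cfg$moisture_range[2] >= 2 ||
      cfg$moisture_range[1] >= cfg$moisture_range[2])
    stop("simConfig: moisture_range must be an increasing interval inside (0, 2)",
         call. = FALSE)
  if (abs(cfg$radiation_moisture_corr) >= 1)
    stop("simConfig: |radiation_moisture_corr| must be < 1", call. = FALSE)
  if (cfg$age_min <= 0 || cfg$age_max < cfg$age_min)
    stop("simConfig: ages must satisfy 0 < age_min <= age_max", call. = FALSE)
  if (cfg$plot_area_min <= 0 || cfg$plot_area_max > 400 ||
      cfg$plot_area_max <= cfg$plot_area_min)
    stop("simConfig: plot areas must lie in (0, 400] m^2", call. = FALSE)
  for (g in c("Acacia", "Eucalyptus", "Other")) {
    td <- cfg$trait_distributions[[g]]
    if (is.null(td) || !all(c("sla", "wood_density", "max_height") %in% names(td)))
      stop("simConfig: trait_distributions must define sla, wood_density and ",
           "max_height for genus ", g, call. = FALSE)
    for (tr in names(td)) {
      if (length(td[[tr]]) != 2L || td[[tr]][2] < 0)
        stop("simConfig: trait distribution for ", g, "/", tr,
             " must be c(meanlog, sdlog >= 0)", call. = FALSE)
    }
  }
  invisible(cfg)
}

#' Default per-genus log-normal trait distributions
#'
#' Species-mean trait distributions chosen so the two focal genera overlap
#' broadly in SLA and wood density while Eucalyptus runs taller, mirroring
#' the contrast between tall myrtaceous trees and shrubbier nitrogen-fixing
#' acacias. Values are (meanlog, sdlog) pairs of log-normals; units are
#' SLA mm^2/g, wood density g/cm^3, maximum height m.
#'
#' @return Named list with components Acacia, Eucalyptus, Other.
#' @export
defaultTraitDistributions <- function() {
  list(
    Acacia = list(sla = c(log(5200), 0.35),
                  wood_density = c(log(0.75), 0.14),
                  max_height = c(log(8), 0.55)),
    Eucalyptus = list(sla = c(log(5600), 0.30),
                      wood_density = c(log(0.66), 0.15),
                      max_height = c(log(19), 0.55)),
    Other = list(sla = c(log(6000), 0.40),
                 wood_density = c(log(0.62), 0.20),
                 max_height = c(log(6), 0.60)))
}

#' Ground-truth coefficient set for growth simulation
#'
#' A `truthSet` pairs fixed-effect coefficients (on the standardized
#' predictor scale used by the model ladder) with the variances of the four
#' random intercepts (subregion, planting, plot, species) and the residual.
#' Coefficients are named by ladder term descriptors such as
#' `"(Intercept)"`, `"sla"`, `"genus:sla"`, `"moisture:density"` or
#' `"genus:moisture:age"`; terms absent from `beta` act as zero.
#'
#' @param beta Named numeric vector of fixed-effect coefficients.
#' @param sigma2_subregion,sigma2_planting,sigma2_plot,sigma2_species
#'   Variances of the random intercepts; must be non-negative.
#' @param sigma2_resid Residual variance; must be non-negative.
#' @return An object of class `truthSet`.
#' @export
truthSet <- function(beta,
                     sigma2_subregion = 0,
                     sigma2_planting = 0,
                     sigma2_plot = 0,
                     sigma2_species = 0,
                     sigma2_resid = 0) {
  if (is.null(names(beta)) || any(!nzchar(names(beta))))
    stop("truthSet: beta must be a fully named numeric vector", call. = FALSE)
  sig <- c(subregion = sigma2_subregion, planting = sigma2_planting,
           plot = sigma2_plot, species = sigma2_species, resid = sigma2_resid)
  if (any(sig < 0)) stop("truthSet: variances must be >= 0", call. = FALSE)
  structure(list(beta = beta, sigma2 = sig), class = "truthSet")
}

#' @export
print.truthSet <- function(x, ...) {
  cat("<truthSet>", length(x$beta), "fixed-effect terms\n")
  cat("  variances:", paste(sprintf("%s=%.3g", names(x$sigma2), x$sigma2),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Default ground truth for the genus-slopes-moisture generating model
#'
#' Coefficient signs follow the qualitative expectations for the system:
#' growth slows with planting age, neighbor density and conspecific
#' proportion, rises with SLA and neighborhood diversity, falls in taller
#' species, and every genus and moisture interaction is set at standardized
#' magnitude 0.05 so the full three-way model is the best-supported member
#' of the ladder at realistic sample sizes. Variance components are
#' calibrated so fixed effects explain roughly a fifth of growth-rate
#' variance and random intercepts roughly a third, echoing the variance
#' partition typical of these plantings.
#'
#' @param interaction_effect Standardized magnitude used for every genus,
#'   moisture and three-way interaction coefficient.
#' @return A [truthSet()].
#' @export
defaultTruth <- function(interaction_effect = 0.05) {
  e <- interaction_effect
  mains <- c(sla = 0.05, wood_density = -0.03, max_height = -0.05,
             moisture = 0.04, radiation = -0.03, age = -0.08,
             plot_area = 0.01, density = -0.06, prop_intra = -0.04,
             richness = 0.03, feve = 0.03, fdis = 0.04)
  beta <- c("(Intercept)" = 0.18, mains, genus = 0.03,
            "plot_area:prop_intra" = -0.02)
  sgn <- rep_len(c(1, -1), length(mains))
  gi <- stats::setNames(sgn * e, paste0("genus:", names(mains)))
  mi <- stats::setNames(rev(sgn)[-1] * e,
                        paste0("moisture:", setdiff(names(mains), "moisture")))
  gmi <- stats::setNames(sgn[-1] * e,
                         paste0("genus:moisture:", setdiff(names(mains), "moisture")))
  truthSet(c(beta, gi, mi, gmi),
           sigma2_subregion = 0.010, sigma2_planting = 0.030,
           sigma2_plot = 0.020, sigma2_species = 0.040,
           sigma2_resid = 0.135)
}

# Stage-level child seeds: a single master seed fans out by fixed offsets so
# each generation stage can be re-run independently yet reproducibly.
childSeed <- function(config, stage) {
  offs <- c(pool = 101L, landscape = 211L, growth = 307L)
  (config$seed + offs[[stage]]) %% .Machine$integer.max
}
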