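#' Generate the species pool with per-genus trait distributions
#'
#' Draws species-mean traits from the per-genus log-normal distributions in
#' the configuration. Focal genera (Acacia, Eucalyptus) are fully measured;
#' "Other" species have each trait masked independently with probability
#' `other_trait_missing`, with per-trait provenance recorded as
#' `"measured"` or `"missing"` so the congener-interpolation step can be
#' exercised downstream.
#'
#' @param config A [simConfig()].
#' @return A `data.frame` with columns species, genus, lifeform, sla,
#'   wood_density, max_height and `<trait>_src` provenance columns.
#' @export
generateSpeciesPool <- function(config) {
  validateSimConfig(config)
  set.seed(childSeed(config, "pool"))
  n <- c(Acacia = config$n_species_acacia,
         Eucalyptus = config$n_species_eucalyptus,
         Other = config$n_species_other)
  prefix <- c(Acacia = "ACA", Eucalyptus = "EUC", Other = "OTH")
  pool <- do.call(rbind, lapply(names(n), function(g) {
    if (n[[g]] == 0L) return(NULL)
    td <- config$trait_distributions[[g]]
    data.frame(
      species = sprintf("%s%03d", prefix[[g]], seq_len(n[[g]])),
      genus = g,
      lifeform = switch(g, Acacia = "shrub", Eucalyptus = "tree",
                        sample(c("tree", "shrub"), n[[g]], replace = TRUE)),
      sla = stats::rlnorm(n[[g]], td$sla[1], td$sla[2]),
      wood_density = stats::rlnorm(n[[g]], td$wood_density[1], td$wood_density[2]),
      max_height = stats::rlnorm(n[[g]], td$max_height[1], td$max_height[2]),
      stringsAsFactors = FALSE)
  }))
  rownames(pool) <- NULL
  for (tr in c("sla", "wood_density", "max_height")) {
    src <- rep("measured", nrow(pool))
    other <- pool$genus == "Other"
    miss <- other & stats::runif(nrow(pool)) < config$other_trait_missing
    pool[[tr]][miss] <- NA_real_
    src[miss] <- "missing"
    pool[[paste0(tr, "_src")]] <- src
  }
  pool
}

# rejection samplers for truncated distributions; vectorised over n
rtruncnorm <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi))
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  x
}

# truncated negative binomial whose *post-truncation* mean equals `mean`:
# the untruncated location is solved by root finding (size is held at the
# value implied by the stated mean/sd)
rtruncnbinom <- function(n, mean, sd, min) {
  v <- sd^2
  if (v <= mean) {                      # not overdispersed: fall back to Poisson
    draw <- function(k, mu) stats::rpois(k, mu)
    etrunc <- function(mu) {
      k <- seq_len(min) - 1L
      p <- stats::dpois(k, mu)
      (mu - sum(k * p)) / (1 - sum(p))
    }
  } else {
    size <- mean^2 / (v - mean)
    draw <- function(k, mu) stats::rnbinom(k, mu = mu, size = size)
    etrunc <- function(mu) {
      k <- seq_len(min) - 1L
      p <- stats::dnbinom(k, mu = mu, size = size)
      (mu - sum(k * p)) / (1 - sum(p))
    }
  }
  mu <- if (min > 0)
    stats::uniroot(function(m) etrunc(m) - mean,
                   c(mean * 1e-3, mean))$root
  else mean
  x <- draw(n, mu)
  while (any(bad <- x < min)) x[bad] <- draw(sum(bad), mu)
  x
}

#' Generate the nested planting / plot / plant landscape
#'
#' Builds the full sampling hierarchy: plantings are scattered over
#' subregions and a geographic window, each carrying a moisture availability
#' ratio (uniform over `moisture_range`), a solar radiation value generated
#' as a Gaussian linear response to moisture calibrated to the configured
#' correlation, and a truncated-normal age. Plots get truncated-normal areas
#' and overdispersed (truncated negative binomial, minimum 2) plant counts.
#' Each plot's species composition is drawn from a planting-level palette
#' via Dirichlet-multinomial weights so conspecific proportions vary, and
#' stem diameters follow a plot-age-dependent log-normal wide enough that
#' back-computed biomass straddles the small-plant exclusion boundary. A
#' small fraction of plants carries a second stem row (multi-stemmed mallee
#' growth form).
#'
#' @param config A [simConfig()].
#' @param species Optional species pool from [generateSpeciesPool()];
#'   generated from `config` when omitted.
#' @return An object of class `revegDataset`: a list with data.frames
#'   `plantings` (planting, subregion, lon, lat, moisture, radiation, age),
#'   `plots` (plot, planting, area), `plants` (one row per stem: plant,
#'   stem, plot, species, diameter, measure_height) and `species`.
#' @export
generateLandscape <- function(config, species = NULL) {
  validateSimConfig(config)
  if (is.null(species)) species <- generateSpeciesPool(config)
  set.seed(childSeed(config, "landscape"))

  np <- config$n_plantings
  m <- stats::runif(np, config$moisture_range[1], config$moisture_range[2])
  sd_m <- diff(config$moisture_range) / sqrt(12)
  r <- config$radiation_moisture_corr
  slope <- r * config$radiation_sd / sd_m
  rad <- config$radiation_mean + slope * (m - mean(config$moisture_range)) +
    stats::rnorm(np, 0, config$radiation_sd * sqrt(1 - r^2))
  rad <- pmax(rad, 1)                   # radiation is physically positive
  plantings <- data.frame(
    planting = sprintf("PL%03d", seq_len(np)),
    subregion = sprintf("SR%02d", sample.int(config$n_subregions, np, replace = TRUE)),
    lon = stats::runif(np, config$lon_range[1], config$lon_range[2]),
    lat = stats::runif(np, config$lat_range[1], config$lat_range[2]),
    moisture = m, radiation = rad,
    age = rtruncnorm(np, config$age_mean, config$age_sd,
                     config$age_min, config$age_max),
    stringsAsFactors = FALSE)

  nplots <- rtruncnbinom(np, config$plots_per_planting_mean,
                         config$plots_per_planting_sd, min = 1)
  plots <- data.frame(
    plot = sprintf("P%04d", seq_len(sum(nplots))),
    planting = rep(plantings$planting, nplots),
    area = rtruncnorm(sum(nplots), config$plot_area_mean, config$plot_area_sd,
                      config$plot_area_min, config$plot_area_max),
    stringsAsFactors = FALSE)

  # planting-level species palettes keep species crossed over plantings
  # while letting plots within a planting share composition
  palette_size <- pmin(nrow(species), 14L)
  palettes <- lapply(seq_len(np), function(i)
    sample(species$species, palette_size))
  names(palettes) <- plantings$planting

  nplants <- rtruncnbinom(nrow(plots), config$plants_per_plot_mean,
                          config$plants_per_plot_sd, min = 2)
  plant_rows <- vector("list", nrow(plots))
  for (i in seq_len(nrow(plots))) {
    pal <- palettes[[plots$planting[i]]]
    k <- round(stats::rnorm(1, config$species_per_plot_mean,
                            config$species_per_plot_sd))
    k <- max(2L, min(as.integer(k), length(pal), nplants[i]))
    spp <- sample(pal, k)
    w <- stats::rgamma(k, shape = 0.8)  # Dirichlet(0.8) composition weights
    counts <- as.vector(stats::rmultinom(1, nplants[i] - k, prob = w / sum(w))) + 1L
    plant_rows[[i]] <- data.frame(plot = plots$plot[i],
                                  species = rep(spp, counts),
                                  stringsAsFactors = FALSE)
  }
  plants <- do.call(rbind, plant_rows)
  plants$plant <- sprintf("T%06d", seq_len(nrow(plants)))

  # diameters: log-normal with age-dependent location so biomass spans the
  # 0.1 kg exclusion boundary under the bundled synthetic allometry
  age_of_plot <- plantings$age[match(plots$planting, plantings$planting)]
  plant_age <- age_of_plot[match(plants$plot, plots$plot)]
  mu_d <- log(5.5) + 0.9 * (log(plant_age) - log(12))
  plants$diameter <- stats::rlnorm(nrow(plants), mu_d, 0.8)
  plants$measure_height <- ifelse(plants$diameter < 1.5, 10,
                                  ifelse(plants$diameter < 5, 50, 130))
  plants$stem <- 1L

  n_multi <- round(config$prop_multi_stem * nrow(plants))
  if (n_multi > 0) {
    idx <- sample.int(nrow(plants), n_multi)
    second <- plants[idx, ]
    second$stem <- 2L
    second$diameter <- second$diameter * stats::runif(n_multi, 0.5, 0.9)
    plants <- rbind(plants, second)
  }
  plants <- plants[order(plants$plant, plants$stem),
                   c("plant", "stem", "plot", "species", "diameter",
                     "measure_height")]
  rownames(plants) <- NULL

  structure(list(plantings = plantings, plots = plots, plants = plants,
                 species = species, config = config),
            class = "revegDataset")
}

#' @export
print.revegDataset <- function(x, ...) {
  cat("<revegDataset>",
      nrow(x$plantings), "plantings /", nrow(x$plots), "plots /",
      length(unique(x$plants$plant)), "plants (",
      nrow(x$species), "species )\n")
  invisible(x)
}

#' Write a synthetic dataset to plain-text files
#'
#' Emits `plantings.csv`, `plots.csv`, `plants.csv`, `species_traits.csv`
#' and, when a truth set is attached, `truth.json`.
#'
#' @param dataset A `revegDataset` (or `revegSim`, see [simulateDataset()]).
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
writeDataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c(plantings = "plantings.csv", plots = "plots.csv",
             plants = "plants.csv", species = "species_traits.csv")
  for (nm in names(files))
    utils::write.csv(dataset[[nm]], file.path(dir, files[[nm]]),
                     row.names = FALSE)
  out <- file.path(dir, files)
  if (!is.null(dataset$truth)) {
    tf <- file.path(dir, "truth.json")
    jsonlite::write_json(list(beta = as.list(dataset$truth$beta),
                              sigma2 = as.list(dataset$truth$sigma2)),
                         tf, auto_unbox = TRUE, digits = NA)
    out <- c(out, tf)
  }
  invisible(out)
}
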