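#' Read an allometric-equation table
#'
#' Allometric equations relate stem diameter D (cm, measured at a stated
#' height above ground) to aboveground biomass B (kg) on the log scale:
#' `ln B = a + b ln D`. Equations are keyed either by species or by life
#' form; species-level entries take precedence when both resolve. The
#' coefficient library itself is external input -- the package bundles a
#' synthetic table (see [defaultAllometry()]) for tests and examples only.
#'
#' @param path CSV file with columns `key` (species name or life-form
#'   label), `level` ("species" or "lifeform"), `measure_height` (cm; one
#'   of 10, 50, 130), `a` (intercept, log-kg) and `b` (slope, > 0).
#' @return A `data.frame` of class `allometryTable`.
#' @export
readAllometry <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("key", "level", "measure_height", "a", "b")
  if (!all(need %in% names(tab)))
    stop("allometry table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (any(tab$b <= 0))
    stop("allometry slopes b must be positive", call. = FALSE)
  class(tab) <- c("allometryTable", "data.frame")
  tab
}

#' Bundled synthetic allometry table
#'
#' A small synthetic coefficient set (life-form level entries for trees and
#' shrubs at the three standard measurement heights, plus a few
#' species-level overrides) used by the data generator and the test suite.
#' It is *not* a validated biomass equation library.
#'
#' @return An `allometryTable`.
#' @export
defaultAllometry <- function() {
  readAllometry(system.file("extdata", "allometry_synthetic.csv",
                            package = "revegrowth", mustWork = TRUE))
}

#' Estimate aboveground biomass from stem diameter
#'
#' Evaluates `B = exp(a + b ln D)` for given coefficients; strictly
#' increasing in D.
#'
#' @param diameter Stem diameter(s) in cm; must be positive.
#' @param a,b Allometric intercept (log-kg) and slope (recycled).
#' @return Biomass in kg.
#' @export
estimateBiomass <- function(diameter, a, b) {
  if (any(!is.finite(diameter)) || any(diameter <= 0))
    stop("estimateBiomass: diameters must be positive", call. = FALSE)
  exp(a + b * log(diameter))
}

# resolve an (species, lifeform, measure_height) triple to allometric
# coefficients; species entries beat life-form fallbacks
resolveAllometry <- function(species, lifeform, measure_height, table) {
  key <- paste(species, measure_height)
  sp <- table[table$level == "species", ]
  lf <- table[table$level == "lifeform", ]
  i <- match(key, paste(sp$key, sp$measure_height))
  j <- match(paste(lifeform, measure_height), paste(lf$key, lf$measure_height))
  a <- ifelse(is.na(i), lf$a[j], sp$a[i])
  b <- ifelse(is.na(i), lf$b[j], sp$b[i])
  if (any(miss <- is.na(a) | is.na(b)))
    stop("no allometric equation resolves for: ",
         paste(unique(key[miss]), collapse = ", "), call. = FALSE)
  data.frame(a = a, b = b)
}

#' Compute per-plant biomass for a stem table
#'
#' Resolves an allometric equation for every stem (species entry preferred,
#' life-form fallback otherwise), evaluates biomass per stem, and sums
#' stems sharing a plant id (multi-stemmed growth forms).
#'
#' @param plants Stem table with columns plant, plot, species, diameter,
#'   measure_height (one row per stem).
#' @param species Species table with columns species, genus, lifeform.
#' @param allometry An `allometryTable`.
#' @return A `data.frame` with one row per plant: plant, plot, species,
#'   genus, biomass (kg).
#' @export
computeBiomass <- function(plants, species, allometry) {
  idx <- match(plants$species, species$species)
  if (anyNA(idx))
    stop("computeBiomass: unknown species in plant table: ",
         paste(unique(plants$species[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  cf <- resolveAllometry(plants$species, species$lifeform[idx],
                         plants$measure_height, allometry)
  stem_b <- estimateBiomass(plants$diameter, cf$a, cf$b)
  agg <- rowsum(stem_b, group = plants$plant)
  first <- !duplicated(plants$plant)
  out <- data.frame(plant = plants$plant[first],
                    plot = plants$plot[first],
                    species = plants$species[first],
                    genus = species$genus[idx][first],
                    stringsAsFactors = FALSE)
  out$biomass <- agg[match(out$plant, rownames(agg)), 1]
  out
}

#' Relative growth rate from biomass and planting age
#'
#' RGR is the natural log of aboveground biomass (kg) divided by planting
#' age (yr), i.e. relative annual biomass increment in kg per kg per year,
#' under the assumption that plants started from (near) zero mass at
#' planting. Negative values are legitimate for sub-kilogram plants.
#'
#' @param biomass Biomass in kg; must be positive.
#' @param age Planting age in yr; must be positive.
#' @return RGR in kg kg^-1 yr^-1.
#' @export
computeRGR <- function(biomass, age) {
  if (any(!is.finite(biomass)) || any(biomass <= 0))
    stop("computeRGR: biomass must be positive", call. = FALSE)
  if (any(!is.finite(age)) || any(age <= 0))
    stop("computeRGR: age must be positive", call. = FALSE)
  log(biomass) / age
}

#' Apply the focal-plant filter
#'
#' Focal plants are Acacia or Eucalyptus individuals with complete
#' species-mean traits. Very small plants (biomass strictly below
#' `min_biomass`, default 0.1 kg) are unlikely to date from the original
#' planting and are excluded from the focal set -- they remain in the data
#' as neighbors.
#'
#' @param plant_biomass Per-plant table from [computeBiomass()].
#' @param species Species table (genus + traits + provenance columns).
#' @param min_biomass Exclusion threshold in kg (strict `<`).
#' @return A list: `focals` (retained focal rows, with an `is_focal` flag
#'   also added to a copy of the input in `plants`), `n_excluded` (count of
#'   focal candidates dropped for small biomass).
#' @export
filterFocals <- function(plant_biomass, species, min_biomass = 0.1) {
  idx <- match(plant_biomass$species, species$species)
  traits_ok <- !is.na(species$sla[idx]) & !is.na(species$wood_density[idx]) &
    !is.na(species$max_height[idx])
  candidate <- plant_biomass$genus %in% c("Acacia", "Eucalyptus") & traits_ok
  small <- candidate & plant_biomass$biomass < min_biomass
  plants <- plant_biomass
  plants$is_focal <- candidate & !small
  list(focals = plants[plants$is_focal, , drop = FALSE],
       plants = plants,
       n_excluded = sum(small))
}

#' Interpolate missing non-focal traits from nearby congeners
#'
#' For each species with a missing trait, the trait is filled with the mean
#' species-level value of congeners occurring in plots within `radius_km`
#' (great-circle/haversine distance) of any plot containing the species.
#' Measured values are never altered; species with no measured congener in
#' radius stay missing and are flagged in the coverage report. Idempotent
#' on a complete table.
#'
#' @param species Species table with traits and `<trait>_src` provenance.
#' @param occurrences data.frame(species, plot) of presences.
#' @param plot_coords data.frame(plot, lon, lat).
#' @param radius_km Search radius in km (default 50).
#' @return The species table with interpolated values, provenance updated
#'   to "interpolated", and a `coverage` attribute: per-trait data.frame of
#'   pre/post coverage fractions plus an `unresolved` data.frame listing
#'   species-trait pairs still missing.
#' @export
interpolateTraits <- function(species, occurrences, plot_coords,
                              radius_km = 50) {
  traits <- c("sla", "wood_density", "max_height")
  plot_ids <- plot_coords$plot
  cm <- as.matrix(plot_coords[, c("lon", "lat")])
  dists <- geosphere::distm(cm, fun = geosphere::distHaversine) / 1000
  near <- dists <= radius_km

  # plots (by index) within radius of any plot holding each species
  occ_idx <- split(match(occurrences$plot, plot_ids), occurrences$species)
  reachable <- lapply(occ_idx, function(ii) {
    ii <- ii[!is.na(ii)]
    if (!length(ii)) return(integer(0))
    which(rowSums(near[, ii, drop = FALSE] > 0) > 0)
  })
  # which species occur in a given set of plots
  sp_of_plot <- split(occurrences$species, match(occurrences$plot, plot_ids))

  out <- species
  pre <- post <- numeric(length(traits))
  unresolved <- list()
  for (t in seq_along(traits)) {
    tr <- traits[t]; src <- paste0(tr, "_src")
    pre[t] <- mean(!is.na(species[[tr]]))
    for (i in which(is.na(species[[tr]]))) {
      sp <- species$species[i]
      plots_near <- reachable[[sp]]
      if (is.null(plots_near) || !length(plots_near)) {
        unresolved[[length(unresolved) + 1L]] <- data.frame(species = sp, trait = tr)
        next
      }
      cand <- unique(unlist(sp_of_plot[as.character(plots_near)]))
      cong <- species$species %in% setdiff(cand, sp) &
        species$genus == species$genus[i] & !is.na(species[[tr]]) &
        species[[src]] == "measured"
      if (!any(cong)) {
        unresolved[[length(unresolved) + 1L]] <- data.frame(species = sp, trait = tr)
        next
      }
      out[[tr]][i] <- mean(species[[tr]][cong])
      out[[src]][i] <- "interpolated"
    }
    post[t] <- mean(!is.na(out[[tr]]))
  }
  attr(out, "coverage") <- list(
    coverage = data.frame(trait = traits, pre = pre, post = post),
    unresolved = if (length(unresolved)) do.call(rbind, unresolved)
                 else data.frame(species = character(0), trait = character(0)))
  out
}
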