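test_that("biomass follows the log-log allometric form", {
  expect_equal(estimateBiomass(1, a = 0, b = 1), 1)
  expect_equal(estimateBiomass(10, a = -2, b = 2.4),
               exp(-2 + 2.4 * log(10)), tolerance = 1e-12)
  # power-law scaling: doubling D multiplies biomass by 2^b
  expect_equal(estimateBiomass(8, a = -1.5, b = 2.4) /
                 estimateBiomass(4, a = -1.5, b = 2.4), 2^2.4)
  expect_error(estimateBiomass(0, a = 0, b = 1), "positive")
  expect_error(estimateBiomass(-3, a = 0, b = 1), "positive")
})

test_that("allometry resolution prefers species entries and sums stems", {
  allom <- defaultAllometry()
  species <- data.frame(species = c("EUC001", "EUC002"),
                        genus = "Eucalyptus", lifeform = "tree")
  plants <- data.frame(plant = c("T1", "T2", "T2"), stem = c(1, 1, 2),
                       plot = "P1", species = c("EUC001", "EUC002", "EUC002"),
                       diameter = c(10, 10, 6), measure_height = 130)
  out <- computeBiomass(plants, species, allom)
  # species-level coefficients for EUC001, life-form fallback for EUC002
  expect_equal(out$biomass[out$plant == "T1"], exp(-1.95 + 2.42 * log(10)))
  expect_equal(out$biomass[out$plant == "T2"],
               exp(-2.0 + 2.4 * log(10)) + exp(-2.0 + 2.4 * log(6)))
  # unresolvable key names the offender
  plants$measure_height <- 99
  expect_error(computeBiomass(plants, species, allom), "99")
})

test_that("biomass round-trips diameters through the inverse form", {
  d <- exp(runif(50, log(0.5), log(40)))
  b <- estimateBiomass(d, a = -2.1, b = 2.35)
  d_back <- exp((log(b) - (-2.1)) / 2.35)
  expect_equal(d_back, d, tolerance = 1e-10)
})

test_that("relative growth rate is ln(biomass)/age", {
  expect_equal(computeRGR(1, 10), 0)
  expect_equal(computeRGR(exp(2), 2), 1)
  expect_equal(computeRGR(0.5, 5), log(0.5) / 5)
  expect_error(computeRGR(0, 5), "positive")
  expect_error(computeRGR(2, 0), "positive")
  # monotone in biomass at fixed age; decreasing in age above 1 kg
  expect_true(all(diff(computeRGR(seq(0.2, 50, length = 20), 8)) > 0))
  expect_true(all(diff(computeRGR(5, seq(4, 30, length = 10))) < 0))
})

test_that("focal filter drops exactly the sub-threshold plants", {
  species <- data.frame(species = c("A1", "E1", "O1"),
                        genus = c("Acacia", "Eucalyptus", "Other"),
                        sla = c(5, 6, NA), wood_density = c(0.7, 0.6, 0.5),
                        max_height = c(8, 20, 5))
  pb <- data.frame(plant = paste0("T", 1:4), plot = "P1",
                   species = c("A1", "A1", "E1", "O1"),
                   genus = c("Acacia", "Acacia", "Eucalyptus", "Other"),
                   biomass = c(0.05, 0.1, 2.0, 0.01))
  res <- filterFocals(pb, species)
  expect_equal(res$n_excluded, 1)                  # strict <: 0.1 kg survives
  expect_setequal(res$focals$plant, c("T2", "T3")) # Other is never focal
  expect_equal(sum(res$plants$is_focal), 2)

  # counting on a generated fixture: 13 of 200 candidates below threshold
  set.seed(4)
  n <- 200
  biom <- c(runif(13, 0.01, 0.0999), runif(n - 13, 0.11, 30))
  pb2 <- data.frame(plant = paste0("T", 1:n), plot = "P1", species = "A1",
                    genus = "Acacia", biomass = sample(biom))
  expect_equal(filterFocals(pb2, species)$n_excluded, 13)
  expect_equal(filterFocals(pb2[pb2$biomass >= 0.1, ], species)$n_excluded, 0)
})

test_that("congener interpolation fills traits from plots within radius", {
  # two plot clusters ~9 km apart, a third ~200 km away
  coords <- data.frame(plot = c("P1", "P2", "P3"),
                       lon = c(145, 145.1, 147), lat = c(-35, -35, -35))
  species <- data.frame(
    species = c("S1", "S2", "S3", "S4"),
    genus = c("G", "G", "G", "G"),
    sla = c(8, 12, NA, NA), wood_density = c(0.5, 0.6, 0.7, 0.4),
    max_height = c(5, 6, 7, 8),
    sla_src = c("measured", "measured", "missing", "missing"),
    wood_density_src = "measured", max_height_src = "measured")
  occ <- data.frame(species = c("S1", "S2", "S3", "S4"),
                    plot = c("P1", "P2", "P2", "P3"))
  out <- interpolateTraits(species, occ, coords, radius_km = 50)
  expect_equal(out$sla[out$species == "S3"], 10)   # mean of 8 and 12
  expect_equal(out$sla_src[out$species == "S3"], "interpolated")
  # S4 only occurs 200 km away: stays missing and is reported
  expect_true(is.na(out$sla[out$species == "S4"]))
  unres <- attr(out, "coverage")$unresolved
  expect_true(any(unres$species == "S4" & unres$trait == "sla"))
  # measured values untouched; idempotent once complete
  expect_equal(out$sla[1:2], c(8, 12))
  again <- interpolateTraits(out, occ, coords, radius_km = 50)
  expect_equal(again$sla, out$sla)
})

test_that("interpolation raises coverage on a generated pool", {
  cfg <- smallConfig(seed = 31, n_species_other = 40,
                     other_trait_missing = 0.5)
  land <- generateLandscape(cfg)
  coords <- merge(land$plots[, c("plot", "planting")],
                  land$plantings[, c("planting", "lon", "lat")])
  occ <- unique(land$plants[, c("species", "plot")])
  out <- interpolateTraits(land$species, occ, coords, radius_km = 50)
  cov <- attr(out, "coverage")$coverage
  expect_true(all(cov$post >= cov$pre))
  expect_gt(sum(cov$post), sum(cov$pre))           # strictly more coverage
  # focal traits are never altered
  focal <- out$genus %in% c("Acacia", "Eucalyptus")
  expect_false(anyNA(out[focal, c("sla", "wood_density", "max_height")]))
})
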