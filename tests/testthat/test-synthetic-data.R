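test_that("configuration is validated", {
  expect_s3_class(simConfig(), "simConfig")
  expect_error(simConfig(n_plantings = 0), "positive")
  expect_error(simConfig(moisture_range = c(0.5, 2.5)), "moisture_range")
  expect_error(simConfig(radiation_moisture_corr = 1), "corr")
  expect_error(simConfig(plot_area_max = 500), "400")
  bad_td <- defaultTraitDistributions()
  bad_td$Acacia$sla <- c(8, -1)
  expect_error(simConfig(trait_distributions = bad_td), "sdlog")
})

test_that("species pool draws from the configured per-genus distributions", {
  cfg <- smallConfig()
  pool <- generateSpeciesPool(cfg)
  expect_identical(pool, generateSpeciesPool(cfg))    # seed contract
  expect_equal(sum(pool$genus == "Acacia"), cfg$n_species_acacia)
  expect_true(all(pool$sla > 0, na.rm = TRUE))
  # focal genera are fully measured, only Other has gaps
  focal <- pool$genus %in% c("Acacia", "Eucalyptus")
  expect_false(anyNA(pool[focal, c("sla", "wood_density", "max_height")]))

  # degenerate scale: every species sits exactly at the genus mean
  td <- defaultTraitDistributions()
  td$Acacia$sla <- c(log(5000), 0)
  p0 <- generateSpeciesPool(smallConfig(trait_distributions = td))
  expect_equal(unique(p0$sla[p0$genus == "Acacia"]), 5000)

  # Monte-Carlo check at 10,000 draws per genus: sample log-mean within
  # 3 standard errors of the configured log-mean
  big <- generateSpeciesPool(simConfig(n_species_acacia = 10000,
                                       n_species_eucalyptus = 10000,
                                       n_species_other = 0, seed = 3))
  for (g in c("Acacia", "Eucalyptus")) {
    for (tr in c("sla", "wood_density", "max_height")) {
      x <- log(big[[tr]][big$genus == g])
      cfg_t <- defaultTraitDistributions()[[g]][[tr]]
      expect_lt(abs(mean(x) - cfg_t[1]), 3 * cfg_t[2] / sqrt(10000))
    }
  }

  # genus trait distributions overlap: both genera have mass in a common interval
  a <- range(big$sla[big$genus == "Acacia"])
  e <- range(big$sla[big$genus == "Eucalyptus"])
  expect_lt(max(a[1], e[1]), min(a[2], e[2]))
})

test_that("landscape respects referential integrity and configured ranges", {
  cfg <- smallConfig(seed = 21)
  land <- generateLandscape(cfg)
  expect_identical(land$plots, generateLandscape(cfg)$plots)
  expect_true(all(land$plots$planting %in% land$plantings$planting))
  expect_true(all(land$plants$plot %in% land$plots$plot))
  expect_true(all(land$plants$species %in% land$species$species))
  expect_true(all(land$plantings$age >= cfg$age_min &
                    land$plantings$age <= cfg$age_max))
  expect_true(all(land$plots$area > 0 & land$plots$area < 400))
  expect_true(all(land$plantings$moisture >= cfg$moisture_range[1] &
                    land$plantings$moisture <= cfg$moisture_range[2]))
  counts <- table(land$plants$plot[!duplicated(land$plants$plant)])
  expect_true(all(counts >= 2))
  expect_setequal(names(counts), land$plots$plot)
})

test_that("solar radiation tracks moisture at the configured correlation", {
  cfg <- simConfig(n_plantings = 500, radiation_moisture_corr = -0.69,
                   seed = 9)
  land <- generateLandscape(cfg)
  r <- cor(land$plantings$moisture, land$plantings$radiation)
  expect_gt(r, -0.75)
  expect_lt(r, -0.63)
})

test_that("growth simulation honours the truth set", {
  sim <- smallSim()
  std <- sim$analysis

  # noise-free limit: growth equals the linear predictor exactly
  tr0 <- truthSet(c("(Intercept)" = 0.2, sla = 0.1, "genus:sla" = 0.05))
  y0 <- simulateGrowth(std, tr0, seed = 1)
  expect_lt(max(abs(y0$rgr - attr(y0, "eta"))), 1e-12)
  X <- model.matrix(~ sla * genus, y0)
  expect_lt(max(abs(y0$rgr - (0.2 + 0.1 * std$sla +
                                0.05 * std$sla * (std$genus == "Eucalyptus")))),
            1e-12)

  # reproducibility and seed sensitivity
  tr1 <- truthSet(c("(Intercept)" = 1), sigma2_resid = 0.01)
  expect_identical(simulateGrowth(std, tr1, seed = 5)$rgr,
                   simulateGrowth(std, tr1, seed = 5)$rgr)
  expect_false(identical(simulateGrowth(std, tr1, seed = 5)$rgr,
                         simulateGrowth(std, tr1, seed = 6)$rgr))

  # CLT check: intercept-only truth with small equal variances
  tr2 <- truthSet(c("(Intercept)" = 1), sigma2_subregion = 0.01,
                  sigma2_planting = 0.01, sigma2_plot = 0.01,
                  sigma2_species = 0.01, sigma2_resid = 0.01)
  y2 <- simulateGrowth(std, tr2, seed = 7)$rgr
  # SE dominated by the highest grouping level (few subregions)
  se <- sqrt(0.01 / length(unique(std$subregion)) + 0.04 / length(y2))
  expect_lt(abs(mean(y2) - 1), 3 * se + 0.05)

  # unknown term names are reported
  expect_error(simulateGrowth(std, truthSet(c(nonexistent = 1)), seed = 1),
               "nonexistent")
})

test_that("dataset files round-trip as plain CSV", {
  sim <- smallSim()
  dir <- withr::local_tempdir()
  files <- writeDataset(sim, dir)
  expect_true(all(file.exists(files)))
  plants <- read.csv(file.path(dir, "plants.csv"))
  expect_equal(nrow(plants), nrow(sim$plants))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"))
  expect_equal(truth$sigma2$resid, unname(sim$truth$sigma2["resid"]))
})
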