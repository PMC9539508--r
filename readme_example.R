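library(revegrowth)
cfg <- simConfig(n_plantings = 40, seed = 1)
sim <- simulateDataset(cfg)
print(sim)
fits_ml <- fitLadder(sim$analysis, method = "ML")
fits_reml <- fitLadder(sim$analysis, method = "REML")
tab <- comparisonTable(fits_ml, fits_reml)[, c(1, 2, 3, 6, 7)]
tab[, -1] <- round(tab[, -1], 3)
print(tab)
nulls <- nullSlopeDistributions(sim$analysis,
                                modelLadder()$genus_slopes_moisture,
                                n_perm = 199, base_seed = 42,
                                observed_fit = fits_reml$genus_slopes_moisture)
rep <- compareAndReport(nulls)
rep[, 4:9] <- round(rep[, 4:9], 3)
print(subset(rep, predictor == "density"))
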