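test_that("noise-free data recover the generating coefficients exactly", {
  sim <- smallSim()
  truth <- truthSet(c("(Intercept)" = 0.2, sla = 0.1, age = -0.08,
                      genus = 0.05, "genus:sla" = 0.04))
  spec <- modelSpec("toy", c("sla", "age", "genus", "genus:sla"))
  d <- simulateGrowth(sim$analysis, truth, seed = 2, spec = spec)
  fit <- fitGrowthModel(d, spec)
  fe <- fixedEffects(fit)
  expect_equal(fe["(Intercept)", "estimate"], 0.2, tolerance = 1e-8)
  expect_equal(fe["sla", "estimate"], 0.1, tolerance = 1e-8)
  i_int <- which(revegrowth:::canonColumn(rownames(fe)) == "genus:sla")
  expect_equal(fe$estimate[i_int], 0.04, tolerance = 1e-8)
  expect_lt(max(varianceComponents(fit)), 1e-8)
})

test_that("REML equals the ANOVA closed form on balanced one-way layouts", {
  spec <- modelSpec("oneway", character(0), random = "group")
  set.seed(123)
  for (i in 1:3) {
    d <- balancedOneWay(k = 40, m = 10)
    mom <- onewayMoM(d)
    fit <- fitGrowthModel(d, spec, method = "REML")
    vc <- varianceComponents(fit)
    expect_equal(unname(vc["group"]), unname(mom["sigma2_g"]), tolerance = 1e-6)
    expect_equal(unname(vc["resid"]), unname(mom["sigma2_e"]), tolerance = 1e-6)
    # REML and ML fixed effects coincide on balanced designs
    fit_ml <- fitGrowthModel(d, spec, method = "ML")
    expect_equal(lme4::fixef(fit$model), lme4::fixef(fit_ml$model),
                 tolerance = 1e-6)
  }
})

test_that("grouping factors with a single level are dropped with a warning", {
  d <- balancedOneWay(k = 20, m = 5)
  d$single <- factor("only")
  spec <- modelSpec("ow2", character(0), random = c("group", "single"))
  expect_warning(fit <- fitGrowthModel(d, spec), "single")
  expect_named(varianceComponents(fit), c("group", "resid"))
})

test_that("AIC counts fixed effects plus variance components", {
  d <- balancedOneWay()
  d$x <- rnorm(nrow(d))
  spec <- modelSpec("ow", "x", random = "group")
  fit_ml <- fitGrowthModel(d, spec, method = "ML")
  ll <- as.numeric(logLik(fit_ml$model))
  k <- 2 + 1 + 1                                   # intercept + slope + 2 variances
  expect_equal(aicML(fit_ml), -2 * ll + 2 * k, tolerance = 1e-10)
  expect_error(aicML(fitGrowthModel(d, spec, method = "REML")), "ML")
})

test_that("likelihood-ratio tests require nesting and are non-negative", {
  d <- balancedOneWay()
  d$x <- rnorm(nrow(d)); d$z <- rnorm(nrow(d))
  s0 <- modelSpec("s0", "x", random = "group")
  s1 <- modelSpec("s1", c("x", "z"), random = "group")
  f0 <- fitGrowthModel(d, s0, method = "ML")
  f1 <- fitGrowthModel(d, s1, method = "ML")
  self <- lrtGrowth(f0, f0)
  expect_equal(self$chi2, 0)
  expect_equal(self$p, 1)
  res <- lrtGrowth(f0, f1)
  expect_gte(res$chi2, 0)
  expect_equal(res$df, 1)
  s2 <- modelSpec("s2", "z", random = "group")
  expect_error(lrtGrowth(fitGrowthModel(d, s2, method = "ML"), f0), "nested")
  expect_error(lrtGrowth(fitGrowthModel(d, s0, method = "REML"),
                         fitGrowthModel(d, s1, method = "REML")), "maximum")
})

test_that("null-data likelihood ratios follow the chi-square reference", {
  # extra terms truly zero: 2*(lnL_big - lnL_small) ~ chi2_df
  spec_s <- modelSpec("s", "x", random = "group")
  spec_b <- modelSpec("b", c("x", paste0("z", 1:4)), random = "group")
  set.seed(55)
  chi2 <- replicate(120, {
    d <- balancedOneWay(k = 25, m = 6)
    d$x <- rnorm(nrow(d)); for (v in paste0("z", 1:4)) d[[v]] <- rnorm(nrow(d))
    d$rgr <- d$rgr + 0.1 * d$x
    lrtGrowth(fitGrowthModel(d, spec_s, method = "ML"),
              fitGrowthModel(d, spec_b, method = "ML"))$chi2
  })
  ks <- suppressWarnings(ks.test(chi2, pchisq, df = 4))
  expect_gt(ks$p.value, 0.01)
})

test_that("pseudo-R2 partitions variance consistently", {
  sim <- smallSim()
  fits <- fitLadder(sim$analysis, method = "REML")
  for (f in fits) {
    r2 <- pseudoR2(f)
    expect_gte(r2[["conditional"]], r2[["marginal"]])
    expect_true(all(r2 >= 0 & r2 <= 1))
  }
  # intercept-only: no fixed variance at all
  expect_equal(pseudoR2(fits$base)[["marginal"]], 0)
  expect_gt(pseudoR2(fits$base)[["conditional"]], 0)
})

test_that("estimates are invariant to row shuffling", {
  sim <- smallSim()
  spec <- modelLadder()$no_genus
  d <- sim$analysis
  f1 <- fitGrowthModel(d, spec)
  set.seed(8)
  f2 <- fitGrowthModel(d[sample(nrow(d)), ], spec)
  # the likelihood is exactly permutation-invariant; agreement between the
  # two fits is limited only by the optimizer's convergence tolerance
  expect_equal(lme4::fixef(f1$model), lme4::fixef(f2$model), tolerance = 1e-4)
  expect_equal(varianceComponents(f1), varianceComponents(f2),
               tolerance = 1e-3)
})

test_that("the comparison table mirrors the three delta-AIC baselines", {
  sim <- smallSim()
  fits_ml <- fitLadder(sim$analysis, method = "ML")
  tab <- comparisonTable(fits_ml)
  expect_named(tab, c("model", "AIC", "dAIC_base", "dAIC_genus_intercepts",
                      "dAIC_no_genus_moisture", "marginal_r2",
                      "conditional_r2"))
  expect_equal(tab$dAIC_base[tab$model == "base"], 0)
  expect_equal(tab$dAIC_base, tab$AIC - tab$AIC[tab$model == "base"])
})
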