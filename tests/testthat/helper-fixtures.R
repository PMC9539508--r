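# Shared small-scale fixtures. A single cached small simulation keeps the
# unit-test suite fast; tests that need special structure build their own.

smallConfig <- function(seed = 11, ...) {
  args <- utils::modifyList(
    list(n_plantings = 12, n_subregions = 4, n_species_acacia = 12,
         n_species_eucalyptus = 20, n_species_other = 8, seed = seed),
    list(...))
  do.call(simConfig, args)
}

.sim_cache <- new.env(parent = emptyenv())

smallSim <- function(seed = 11) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulateDataset(smallConfig(seed))
  .sim_cache[[key]]
}

# one cached study-scale dataset (default design) shared by tests that need
# realistic planting-level structure
defaultSim <- function(seed = 101) {
  key <- paste0("d", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulateDataset(simConfig(seed = seed))
  .sim_cache[[key]]
}

# balanced one-way layout: k groups of size m with a single random intercept
balancedOneWay <- function(k = 40, m = 10, sigma_g = 0.5, sigma_e = 0.3,
                           mu = 1) {
  g <- factor(rep(seq_len(k), each = m))
  data.frame(rgr = mu + rnorm(k, 0, sigma_g)[g] + rnorm(k * m, 0, sigma_e),
             group = g)
}

# ANOVA method-of-moments closed form for the balanced one-way layout
onewayMoM <- function(data) {
  m <- as.numeric(table(data$group)[1])
  means <- tapply(data$rgr, data$group, mean)
  msb <- m * stats::var(means)
  msw <- mean(tapply(data$rgr, data$group, stats::var))
  c(sigma2_g = (msb - msw) / m, sigma2_e = msw)
}
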