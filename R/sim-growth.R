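# map truth term descriptors (e.g. "genus:moisture:sla") onto design-matrix
# column names (e.g. "moisture:sla:genusEucalyptus"): compare colon-split
# component sets with the genus factor canonicalised
canonColumn <- function(x) {
  parts <- strsplit(x, ":", fixed = TRUE)
  vapply(parts, function(p) {
    p[p == "genusEucalyptus"] <- "genus"
    paste(sort(p), collapse = ":")
  }, character(1))
}

matchTermColumns <- function(terms, colnames) {
  i <- match(canonColumn(terms), canonColumn(colnames))
  stats::setNames(i, terms)
}

#' Simulate growth rates from a ground-truth coefficient set
#'
#' Generates the response on the standardized predictor scale:
#' `rgr = X beta + u_subregion + u_planting + u_plot + u_species + eps`,
#' where X is the fixed-effect design of `spec` built from `data`, each
#' `u` is one Gaussian intercept draw per group level, and `eps` is iid
#' Gaussian residual noise. Terms named in the truth that the spec's
#' design does not contain raise an error listing the unknown names; spec
#' terms absent from the truth act as zero. The realized random intercepts
#' are stored in the `ranef_true` attribute for recovery tests.
#'
#' @param data Standardized analysis table (with grouping columns).
#' @param truth A [truthSet()].
#' @param seed Integer seed for the random draws.
#' @param spec `modelSpec` whose design carries the truth terms (default
#'   the genus-slopes-moisture ladder member).
#' @return `data` with a simulated `rgr` column; attributes `ranef_true`
#'   (list of per-level draws) and `eta` (the linear predictor).
#' @export
simulateGrowth <- function(data, truth, seed,
                           spec = modelLadder()$genus_slopes_moisture) {
  stopifnot(inherits(truth, "truthSet"))
  X <- stats::model.matrix(specFormula(spec, response = NULL, random = FALSE),
                           data = data)
  idx <- matchTermColumns(names(truth$beta), colnames(X))
  if (anyNA(idx))
    stop("simulateGrowth: truth names unknown terms: ",
         paste(names(truth$beta)[is.na(idx)], collapse = ", "), call. = FALSE)
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  beta[idx] <- truth$beta
  eta <- as.vector(X %*% beta)

  set.seed(seed)
  groups <- list(subregion = data$subregion, planting = data$planting,
                 plot = data$plot, species = data$species)
  u <- list()
  y <- eta
  for (g in names(groups)) {
    lev <- unique(groups[[g]])
    draw <- stats::rnorm(length(lev), 0, sqrt(truth$sigma2[[g]]))
    names(draw) <- lev
    u[[g]] <- draw
    y <- y + draw[groups[[g]]]
  }
  y <- y + stats::rnorm(length(y), 0, sqrt(truth$sigma2[["resid"]]))
  data$rgr <- as.vector(y)
  attr(data, "ranef_true") <- u
  attr(data, "eta") <- eta
  data
}

#' Simulate a complete analysis-ready dataset
#'
#' Runs the whole generative pipeline: species pool, landscape, per-plant
#' biomass under the bundled synthetic allometry, focal filtering,
#' neighborhood metrics, predictor assembly, transformation and
#' standardization, then growth simulation under `truth`. The result is
#' the package's standard test bench: a dataset with known coefficients
#' and known random-intercept draws.
#'
#' @param config A [simConfig()].
#' @param truth A [truthSet()] (default [defaultTruth()]).
#' @param spec Generating `modelSpec` (default genus_slopes_moisture).
#' @param allometry Allometry table (default the bundled synthetic one).
#' @return Object of class `revegSim`: the `revegDataset` components plus
#'   `focals` (per-plant biomass/focal flags), `n_excluded`, `analysis`
#'   (standardized complete-case analysis table with simulated `rgr` and
#'   observed `rgr_obs`), `scaling`, `truth` and `spec`.
#' @export
simulateDataset <- function(config, truth = defaultTruth(),
                            spec = modelLadder()$genus_slopes_moisture,
                            allometry = defaultAllometry()) {
  dataset <- generateLandscape(config)
  pb <- computeBiomass(dataset$plants, dataset$species, allometry)
  ff <- filterFocals(pb, dataset$species)
  metrics <- neighborhoodMetrics(dataset, ff$focals)
  raw <- predictorTable(dataset, ff$focals, metrics)
  raw$biomass <- ff$focals$biomass[match(raw$plant, ff$focals$plant)]
  raw$rgr_obs <- computeRGR(raw$biomass, raw$age)
  keep <- stats::complete.cases(raw[, continuousPredictors()])
  trans <- transformPredictors(raw[keep, , drop = FALSE])
  std <- standardizePredictors(trans)
  std <- simulateGrowth(std, truth, seed = childSeed(config, "growth"),
                        spec = spec)
  structure(c(dataset,
              list(focal_plants = ff$plants, n_excluded = ff$n_excluded,
                   analysis = std, scaling = attr(std, "scaling"),
                   truth = truth, spec = spec)),
            class = c("revegSim", "revegDataset"))
}

#' @export
print.revegSim <- function(x, ...) {
  cat("<revegSim>", nrow(x$plantings), "plantings /", nrow(x$plots),
      "plots /", nrow(x$analysis), "focals in the analysis table;",
      x$n_excluded, "small focals excluded\n")
  invisible(x)
}
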