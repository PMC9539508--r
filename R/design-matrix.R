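#' Continuous predictors of the growth models
#'
#' The twelve continuous fixed effects entering the model ladder: the three
#' species-mean traits (sla, wood_density, max_height), the two climate
#' variables (moisture, radiation), the two planting characteristics (age,
#' plot_area) and the five neighborhood attributes (density, prop_intra,
#' richness, feve, fdis).
#'
#' @return Character vector of predictor names.
#' @export
continuousPredictors <- function() {
  c("sla", "wood_density", "max_height", "moisture", "radiation",
    "age", "plot_area", "density", "prop_intra", "richness", "feve", "fdis")
}

#' Assemble the per-focal analysis table
#'
#' Joins focal identities (plant, species, genus, plot, planting,
#' subregion), planting-level climate and age, plot area, focal species
#' traits and the neighborhood metrics into one raw (untransformed)
#' predictor table. When the focal table carries a `biomass` column an
#' observed relative growth rate `rgr_obs = ln(biomass)/age` is attached.
#'
#' @param dataset A `revegDataset`.
#' @param focals Focal table from [filterFocals()].
#' @param metrics Output of [neighborhoodMetrics()].
#' @return data.frame, one row per focal, with id columns, `genus` as a
#'   factor (Acacia reference), raw predictors, and `rgr_obs` if available.
#' @export
predictorTable <- function(dataset, focals, metrics) {
  pl <- dataset$plots
  pt <- dataset$plantings
  sp <- dataset$species
  plot_i <- match(focals$plot, pl$plot)
  pt_i <- match(pl$planting[plot_i], pt$planting)
  sp_i <- match(focals$species, sp$species)
  m_i <- match(focals$plant, metrics$plant)
  out <- data.frame(
    plant = focals$plant, plot = focals$plot,
    planting = pl$planting[plot_i], subregion = pt$subregion[pt_i],
    species = focals$species,
    genus = factor(focals$genus, levels = c("Acacia", "Eucalyptus")),
    sla = sp$sla[sp_i], wood_density = sp$wood_density[sp_i],
    max_height = sp$max_height[sp_i],
    moisture = pt$moisture[pt_i], radiation = pt$radiation[pt_i],
    age = pt$age[pt_i], plot_area = pl$area[plot_i],
    density = metrics$density[m_i], prop_intra = metrics$prop_intra[m_i],
    richness = metrics$richness[m_i], feve = metrics$feve[m_i],
    fdis = metrics$fdis[m_i],
    stringsAsFactors = FALSE)
  if (!is.null(focals$biomass))
    out$rgr_obs <- computeRGR(focals$biomass, out$age)
  out
}

#' Transform predictors ahead of standardization
#'
#' Natural-log transforms planting age, maximum height and solar radiation
#' and square-root transforms neighbor density, to linearize their
#' bivariate relationships with growth rate. All other continuous
#' predictors pass through unchanged. Transformation always precedes
#' standardization.
#'
#' @param data Raw predictor table from [predictorTable()].
#' @return The table with `age`, `max_height`, `radiation` log-transformed
#'   and `density` square-root transformed.
#' @export
transformPredictors <- function(data) {
  for (v in c("age", "max_height", "radiation")) {
    bad <- which(!is.na(data[[v]]) & data[[v]] <= 0)
    if (length(bad))
      stop("transformPredictors: non-positive ", v, " in rows ",
           paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
    data[[v]] <- log(data[[v]])
  }
  bad <- which(!is.na(data$density) & data$density < 0)
  if (length(bad))
    stop("transformPredictors: negative density in rows ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  data$density <- sqrt(data$density)
  attr(data, "transformed") <- TRUE
  data
}

#' Standardize predictors to zero mean and unit standard deviation
#'
#' Z-scores each listed column using the sample (n-1) standard deviation,
#' pooling both genera so genus-specific partial slopes stay directly
#' comparable on a common scale. The applied centers and scales are stored
#' so raw-scale values (e.g. a moisture availability of 0.27) can be mapped
#' onto the standardized scale later.
#'
#' @param data Transformed predictor table.
#' @param columns Columns to standardize (default all continuous
#'   predictors present in the table).
#' @return The table with standardized columns and a `scaling` attribute of
#'   class `predictorScaling` (named centers and scales).
#' @export
standardizePredictors <- function(data, columns = intersect(continuousPredictors(),
                                                            names(data))) {
  center <- scale <- stats::setNames(numeric(length(columns)), columns)
  for (v in columns) {
    x <- data[[v]]
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0)
      stop("standardizePredictors: column '", v, "' is constant", call. = FALSE)
    center[v] <- mean(x, na.rm = TRUE)
    scale[v] <- s
    data[[v]] <- (x - center[v]) / s
  }
  attr(data, "scaling") <- structure(list(center = center, scale = scale),
                                     class = "predictorScaling")
  data
}

#' Map a raw predictor value to the standardized scale
#'
#' @param scaling A `predictorScaling` (the `scaling` attribute left by
#'   [standardizePredictors()]).
#' @param variable Predictor name.
#' @param value Raw value(s) on the *transformed* scale (i.e. after any
#'   log/sqrt transform; moisture is untransformed).
#' @return Standardized (z) value(s).
#' @export
scaleValue <- function(scaling, variable, value) {
  if (!variable %in% names(scaling$center))
    stop("no stored scaling for '", variable, "'", call. = FALSE)
  (value - scaling$center[[variable]]) / scaling$scale[[variable]]
}

#' The seven-model ladder
#'
#' Builds the nested sequence of fixed-effect specifications used to ask
#' whether genus identity and moisture availability modulate growth-rate
#' correlates:
#' \describe{
#'   \item{base}{intercept only;}
#'   \item{no_genus}{all continuous predictors (plus the retained
#'     plot_area x prop_intra interaction);}
#'   \item{genus_intercepts}{adds a genus main effect;}
#'   \item{genus_slopes}{adds genus x predictor two-way interactions;}
#'   \item{no_genus_moisture, genus_intercepts_moisture}{add moisture x
#'     predictor two-way interactions to the corresponding model;}
#'   \item{genus_slopes_moisture}{adds genus x moisture x predictor
#'     three-way interactions (with all lower-order terms by marginality).}
#' }
#' All specs share the four crossed/nested random intercepts (subregion,
#' planting, plot, species). Functional range is deliberately never a term.
#'
#' @return Named list of seven `modelSpec` objects, in ladder order.
#' @export
modelLadder <- function() {
  mains <- continuousPredictors()
  others <- setdiff(mains, "moisture")
  area_int <- "plot_area:prop_intra"
  no_genus <- c(mains, area_int)
  genus_int <- c(no_genus, "genus")
  genus_slp <- c(genus_int, paste0("genus:", mains))
  moist2 <- paste0("moisture:", others)
  specs <- list(
    base = character(0),
    no_genus = no_genus,
    genus_intercepts = genus_int,
    genus_slopes = genus_slp,
    no_genus_moisture = c(no_genus, moist2),
    genus_intercepts_moisture = c(genus_int, moist2),
    genus_slopes_moisture = c(genus_slp, moist2,
                              paste0("genus:moisture:", others)))
  lapply(names(specs), function(nm) modelSpec(nm, specs[[nm]])) |>
    stats::setNames(names(specs))
}

#' Construct a model specification
#'
#' @param name Model name.
#' @param fixed Character vector of fixed-effect terms (empty = intercept
#'   only).
#' @param random Grouping factors receiving random intercepts.
#' @return An object of class `modelSpec`.
#' @export
modelSpec <- function(name, fixed,
                      random = c("subregion", "planting", "plot", "species")) {
  structure(list(name = name, fixed = fixed, random = random),
            class = "modelSpec")
}

#' @export
print.modelSpec <- function(x, ...) {
  cat("<modelSpec>", x$name, "-", length(x$fixed), "fixed terms,",
      "random intercepts:", paste(x$random, collapse = " + "), "\n")
  invisible(x)
}

#' Model formula of a specification
#'
#' @param spec A `modelSpec`.
#' @param response Response variable name (default `"rgr"`; `NULL` for a
#'   one-sided formula).
#' @param random Include the random-intercept terms (set `FALSE` for a
#'   fixed-effects-only formula, e.g. to build a design matrix).
#' @return A formula.
#' @export
specFormula <- function(spec, response = "rgr", random = TRUE) {
  terms <- spec$fixed
  if (random)
    terms <- c(terms, sprintf("(1 | %s)", spec$random))
  if (!length(terms)) terms <- "1"
  stats::reformulate(terms, response = response, env = globalenv())
}

# does `small` nest inside `big`? (term sets, order-free within ':')
canonTerms <- function(terms) {
  vapply(strsplit(terms, ":", fixed = TRUE),
         function(p) paste(sort(p), collapse = ":"), character(1))
}

#' @rdname specFormula
#' @param small,big Two `modelSpec`s.
#' @return `isNested()`: `TRUE` if every term of `small` appears in `big`.
#' @export
isNested <- function(small, big) {
  all(canonTerms(small$fixed) %in% canonTerms(big$fixed))
}

#' Variance inflation factors
#'
#' For each column j of a continuous main-effects design, regresses it on
#' the remaining columns and reports `VIF_j = 1 / (1 - R_j^2)`. Warns when
#' any VIF reaches 3, the screening threshold used before model fitting.
#'
#' @param data Predictor table (or matrix); only `columns` are used, rows
#'   with missing values dropped.
#' @param columns Columns to screen (default the continuous predictors).
#' @return Named vector of VIFs.
#' @export
vif <- function(data, columns = intersect(continuousPredictors(), colnames(data))) {
  X <- as.matrix(as.data.frame(data)[, columns, drop = FALSE])
  X <- X[stats::complete.cases(X), , drop = FALSE]
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    drop <- columns[qrX$pivot[-seq_len(qrX$rank)] - 1L]
    stop("vif: design is rank deficient; collinear set includes: ",
         paste(drop, collapse = ", "), call. = FALSE)
  }
  out <- vapply(seq_along(columns), function(j) {
    r2 <- summary(stats::lm(X[, j] ~ X[, -j]))$r.squared
    1 / (1 - r2)
  }, numeric(1))
  names(out) <- columns
  if (any(out >= 3))
    warning("VIF >= 3 for: ",
            paste(columns[out >= 3], collapse = ", "), call. = FALSE)
  out
}

#' Plot-area interaction screen
#'
#' Plot area is a covariate for unstandardized plot sizes; as a
#' pre-analysis, every other predictor is allowed to interact with plot
#' area in an extension of the no-genus model, and interactions with
#' |z| >= `z_threshold` are reported for retention. In the default ladder
#' only plot_area x prop_intra is retained.
#'
#' @param data Standardized analysis table with an `rgr` column.
#' @param z_threshold Retention threshold on |estimate/SE| (default 1.96).
#' @return data.frame of plot-area interaction terms with estimates, SEs,
#'   z values and a `retain` flag.
#' @export
plotAreaScreen <- function(data, z_threshold = 1.96) {
  others <- setdiff(continuousPredictors(), "plot_area")
  spec <- modelSpec("area_screen",
                    c(continuousPredictors(), paste0("plot_area:", others)))
  fit <- fitGrowthModel(data, spec, method = "REML")
  cf <- fixedEffects(fit)
  keep <- grepl("plot_area:", rownames(cf)) | grepl(":plot_area", rownames(cf))
  out <- data.frame(term = rownames(cf)[keep],
                    estimate = cf$estimate[keep], se = cf$se[keep])
  out$z <- out$estimate / out$se
  out$retain <- abs(out$z) >= z_threshold
  out
}
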