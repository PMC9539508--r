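#' Permute growth rates across focal plants
#'
#' Uniform random permutation of the response over the whole focal dataset
#' (deliberately *not* stratified by plot, planting or genus), destroying
#' every predictor-growth association while preserving the growth-rate
#' multiset exactly.
#'
#' @param y Growth-rate vector.
#' @param seed Integer seed.
#' @return Permuted vector.
#' @export
permuteGrowth <- function(y, seed) {
  set.seed(seed)
  y[sample.int(length(y))]
}

#' Dry and mesic moisture evaluation conditions
#'
#' Builds the two moisture-availability conditions at which genus-specific
#' partial slopes of the moisture-interaction model are evaluated. By
#' default they are the 10th and 90th quantiles of the dataset's raw
#' moisture values; fixed raw values (e.g. the conventional 0.27 / 0.76)
#' can be supplied instead. Raw values are mapped to the standardized
#' scale through the stored predictor scaling.
#'
#' @param scaling A `predictorScaling`.
#' @param moisture_raw Raw moisture values of the dataset (used for the
#'   quantile default).
#' @param values Optional named raw values `c(dry = , mesic = )`
#'   overriding the quantiles.
#' @param probs Quantile pair used when `values` is NULL.
#' @return data.frame with columns label, raw, z (dry first).
#' @export
moistureConditions <- function(scaling, moisture_raw = NULL, values = NULL,
                               probs = c(0.1, 0.9)) {
  if (is.null(values)) {
    if (is.null(moisture_raw))
      stop("moistureConditions: supply either moisture_raw or values",
           call. = FALSE)
    values <- stats::quantile(moisture_raw, probs, names = FALSE)
    names(values) <- c("dry", "mesic")
  }
  if (values[["dry"]] >= values[["mesic"]])
    stop("moistureConditions: dry must be below mesic", call. = FALSE)
  data.frame(label = names(values), raw = as.numeric(values),
             z = scaleValue(scaling, "moisture", as.numeric(values)),
             stringsAsFactors = FALSE)
}

# contrast vector for the partial slope of `predictor` for `genus` at
# standardized moisture `moisture_z` (NULL for non-moisture models)
slopeContrast <- function(coef_names, predictor, genus, moisture_z = NULL) {
  canon <- canonColumn(coef_names)
  ct <- stats::setNames(numeric(length(coef_names)), coef_names)
  pick <- function(parts) which(canon == paste(sort(parts), collapse = ":"))
  add <- function(parts, w) {
    i <- pick(parts)
    if (length(i)) ct[i] <<- ct[i] + w
    length(i) > 0
  }
  if (!add(predictor, 1))
    stop("predictor '", predictor, "' absent from the fitted model",
         call. = FALSE)
  if (genus == "Eucalyptus") add(c("genus", predictor), 1)
  if (!is.null(moisture_z) && predictor != "moisture") {
    add(c("moisture", predictor), moisture_z)
    if (genus == "Eucalyptus") add(c("genus", "moisture", predictor), moisture_z)
  }
  ct
}

#' Genus-specific partial regression slope
#'
#' The slope of a predictor for a given genus, holding every other
#' predictor at its (zero, standardized) mean: the linear combination of
#' the main effect, the genus interaction and -- for moisture models,
#' evaluated at a standardized moisture value -- the moisture and
#' genus-by-moisture interaction coefficients. The standard error comes
#' from the coefficient covariance (delta method on a linear combination).
#' With Acacia as reference level, the Eucalyptus slope is
#' `beta_pred + beta_pred:genus (+ m_z * (beta_pred:moisture +
#' beta_pred:genus:moisture))`; reporting slopes as linear combinations
#' keeps them invariant to the factor coding.
#'
#' @param fit A `growthFit` of a genus-slopes specification.
#' @param predictor Continuous predictor name.
#' @param genus "Acacia" or "Eucalyptus".
#' @param moisture_z Standardized moisture value, or NULL for models
#'   without moisture interactions.
#' @return Named vector `c(slope, se)`.
#' @export
partialSlope <- function(fit, predictor, genus = c("Acacia", "Eucalyptus"),
                         moisture_z = NULL) {
  genus <- match.arg(genus)
  b <- lme4::fixef(fit$model)
  ct <- slopeContrast(names(b), predictor, genus, moisture_z)
  V <- as.matrix(stats::vcov(fit$model))
  c(slope = sum(ct * b), se = sqrt(drop(ct %*% V %*% ct)))
}

# all (predictor x genus x condition) slope statistics for one coefficient
# vector; returns named numeric vector
slopeStats <- function(coef_names, coefs, predictors, conditions = NULL) {
  out <- c()
  for (p in predictors) {
    for (g in c("Acacia", "Eucalyptus")) {
      if (is.null(conditions)) {
        ct <- slopeContrast(coef_names, p, g, NULL)
        out[paste(p, g, sep = ".")] <- sum(ct * coefs)
      } else {
        for (k in seq_len(nrow(conditions))) {
          ct <- slopeContrast(coef_names, p, g, conditions$z[k])
          out[paste(p, g, conditions$label[k], sep = ".")] <- sum(ct * coefs)
        }
      }
    }
  }
  out
}

#' Permutation null distributions for partial slopes
#'
#' Shuffles growth rates across all focal plants `n_perm` times, refits the
#' model (random effects re-estimated each time) on every permuted
#' response, and extracts each genus-specific standardized partial slope
#' (per moisture condition for the moisture model). Per-permutation seeds
#' are `base_seed + i`. Permutation fits that fail to converge are dropped
#' and counted; more than `max_fail` of them aborts with diagnostics.
#'
#' Empirical p-values are two-sided with the add-one correction:
#' `p = (1 + #(|null| >= |observed|)) / (n_kept + 1)`, so p is never 0.
#'
#' @param data Standardized analysis table with `rgr`.
#' @param spec `modelSpec`: one of the genus-slopes ladder members.
#' @param n_perm Number of permutations (default 1000).
#' @param base_seed Integer base seed.
#' @param conditions Moisture conditions from [moistureConditions()];
#'   required for (and only for) moisture-interaction specs. When omitted
#'   for such a spec, dataset 10/90 quantiles are used.
#' @param predictors Predictors to track (default all continuous ones).
#' @param max_fail Maximum tolerated fraction of non-converged permutation
#'   fits (default 0.01).
#' @param observed_fit Optional pre-computed observed `growthFit`.
#' @return Object of class `nullSlopes`: list with `samples` (matrix
#'   n_kept x statistics), `observed`, `se_observed`, `interval` (2.5 and
#'   97.5 percentiles), `null_mean`, `null_sd`, `p`, `n_perm`,
#'   `n_dropped`, `conditions`, `spec_name`.
#' @export
nullSlopeDistributions <- function(data, spec, n_perm = 1000, base_seed = 1,
                                   conditions = NULL,
                                   predictors = intersect(continuousPredictors(),
                                                          names(data)),
                                   max_fail = 0.01,
                                   observed_fit = NULL) {
  has_moisture <- any(grepl("moisture:", spec$fixed))
  if (is.null(observed_fit))
    observed_fit <- fitGrowthModel(data, spec, method = "REML")
  if (has_moisture && is.null(conditions))
    conditions <- moistureConditions(observed_fit$scaling,
                                     moisture_raw = rawMoisture(data,
                                                                observed_fit$scaling))
  if (!has_moisture) conditions <- NULL

  b_obs <- lme4::fixef(observed_fit$model)
  obs <- slopeStats(names(b_obs), b_obs, predictors, conditions)
  V <- as.matrix(stats::vcov(observed_fit$model))
  se_obs <- vapply(names(obs), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    mz <- if (is.null(conditions)) NULL
          else conditions$z[match(parts[3], conditions$label)]
    ct <- slopeContrast(names(b_obs), parts[1], parts[2], mz)
    sqrt(drop(ct %*% V %*% ct))
  }, numeric(1))

  model_rows <- stats::complete.cases(
    data[, c(all.vars(specFormula(spec)), "rgr")[-1]])
  y <- data$rgr
  samples <- matrix(NA_real_, n_perm, length(obs),
                    dimnames = list(NULL, names(obs)))
  dropped <- 0L
  for (i in seq_len(n_perm)) {
    yp <- permuteGrowth(y, seed = base_seed + i)
    fit_i <- suppressMessages(suppressWarnings(
      lme4::refit(observed_fit$model, newresp = yp[model_rows])))
    ok <- fit_i@optinfo$conv$opt == 0
    if (!ok) { dropped <- dropped + 1L; next }
    b <- lme4::fixef(fit_i)
    samples[i, ] <- slopeStats(names(b), b, predictors, conditions)
  }
  if (dropped / n_perm > max_fail)
    stop("nullSlopeDistributions: ", dropped, " of ", n_perm,
         " permutation fits failed to converge", call. = FALSE)
  samples <- samples[stats::complete.cases(samples), , drop = FALSE]

  interval <- apply(samples, 2, stats::quantile, probs = c(0.025, 0.975))
  p <- vapply(seq_along(obs), function(j)
    (1 + sum(abs(samples[, j]) >= abs(obs[j]))) / (nrow(samples) + 1),
    numeric(1))
  names(p) <- names(obs)
  structure(list(samples = samples, observed = obs, se_observed = se_obs,
                 interval = interval,
                 null_mean = colMeans(samples),
                 null_sd = apply(samples, 2, stats::sd),
                 p = p, n_perm = n_perm, n_dropped = dropped,
                 conditions = conditions, spec_name = spec$name),
            class = "nullSlopes")
}

# recover raw moisture values from a standardized column
rawMoisture <- function(data, scaling) {
  data$moisture * scaling$scale[["moisture"]] + scaling$center[["moisture"]]
}

#' @export
print.nullSlopes <- function(x, ...) {
  cat("<nullSlopes>", x$spec_name, "-", ncol(x$samples),
      "slope statistics x", nrow(x$samples), "permutations (",
      x$n_dropped, "dropped )\n")
  invisible(x)
}

#' Compare observed slopes with their permutation nulls
#'
#' Emits the machine-readable analogue of slope-versus-null interval
#' figures: one row per predictor x genus (x moisture condition), with the
#' observed standardized partial slope, its SE, the null 95% percentile
#' interval, an inside/outside flag and the empirical p-value.
#'
#' @param nulls A `nullSlopes` object.
#' @return data.frame with columns predictor, genus, condition, observed,
#'   se, null_lo, null_hi, null_sd, p, flag ("significant" when the
#'   observed slope falls outside the null interval, "ns" otherwise).
#' @export
compareAndReport <- function(nulls) {
  nm <- colnames(nulls$samples)
  parts <- strsplit(nm, ".", fixed = TRUE)
  out <- data.frame(
    predictor = vapply(parts, `[`, "", 1),
    genus = vapply(parts, `[`, "", 2),
    condition = vapply(parts, function(p) if (length(p) > 2) p[3] else "all", ""),
    observed = as.numeric(nulls$observed),
    se = as.numeric(nulls$se_observed),
    null_lo = nulls$interval[1, ], null_hi = nulls$interval[2, ],
    null_sd = as.numeric(nulls$null_sd),
    p = as.numeric(nulls$p),
    stringsAsFactors = FALSE)
  out$flag <- ifelse(out$observed < out$null_lo | out$observed > out$null_hi,
                     "significant", "ns")
  rownames(out) <- NULL
  out
}
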