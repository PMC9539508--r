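#' Fit a growth-rate linear mixed model
#'
#' Fits `rgr ~ fixed terms + (1|subregion) + (1|planting) + (1|plot) +
#' (1|species)` by REML (for reported estimates) or ML (for AIC and
#' likelihood-ratio comparison). The species intercept is crossed with the
#' nested spatial intercepts. Grouping factors with fewer than two observed
#' levels are dropped with a warning. Rows with missing response or
#' predictors are dropped before fitting (lme4's `na.omit`), so ladder
#' members should be compared on a common complete-case table.
#'
#' @param data Standardized analysis table (see [standardizePredictors()]);
#'   must contain `response` and the grouping columns.
#' @param spec A [modelSpec()].
#' @param method "REML" or "ML".
#' @param response Response column (default `"rgr"`).
#' @return Object of class `growthFit`: list with the fitted `merMod`
#'   (`model`), `spec`, `method`, `converged`, `singular` flags and the
#'   `scaling` attribute carried over from `data` when present.
#' @export
fitGrowthModel <- function(data, spec, method = c("REML", "ML"),
                           response = "rgr") {
  method <- match.arg(method)
  stopifnot(inherits(spec, "modelSpec"))
  random <- spec$random
  for (g in spec$random) {
    if (length(unique(data[[g]])) < 2) {
      warning("dropping random intercept for '", g,
              "': fewer than 2 levels", call. = FALSE)
      random <- setdiff(random, g)
    }
  }
  spec2 <- spec; spec2$random <- random
  form <- specFormula(spec2, response = response)
  fit <- suppressMessages(lme4::lmer(
    form, data = data, REML = (method == "REML"),
    control = lme4::lmerControl(calc.derivs = FALSE,
                                check.conv.singular = "ignore")))
  conv <- fit@optinfo$conv$opt == 0 &&
    length(fit@optinfo$conv$lme4$messages) == 0
  structure(list(model = fit, spec = spec2, method = method,
                 response = response,
                 converged = conv, singular = lme4::isSingular(fit),
                 scaling = attr(data, "scaling")),
            class = "growthFit")
}

#' @export
print.growthFit <- function(x, ...) {
  cat("<growthFit>", x$spec$name, paste0("(", x$method, ")"),
      "-", length(lme4::fixef(x$model)), "fixed effects;",
      "logLik", format(as.numeric(stats::logLik(x$model)), digits = 8), "\n")
  invisible(x)
}

#' Fixed-effect estimates of a growth fit
#'
#' @param fit A `growthFit`.
#' @return data.frame with rownames = coefficient names and columns
#'   `estimate`, `se`.
#' @export
fixedEffects <- function(fit) {
  b <- lme4::fixef(fit$model)
  V <- as.matrix(stats::vcov(fit$model))
  data.frame(estimate = b, se = sqrt(diag(V)), row.names = names(b))
}

#' Random-intercept and residual variance components
#'
#' @param fit A `growthFit`.
#' @return Named vector: one variance per retained grouping factor plus
#'   `resid`. Boundary estimates come back as (numerical) zero.
#' @export
varianceComponents <- function(fit) {
  vc <- lme4::VarCorr(fit$model)
  out <- vapply(fit$spec$random, function(g) {
    if (g %in% names(vc)) as.numeric(vc[[g]][1, 1]) else 0
  }, numeric(1))
  c(out, resid = stats::sigma(fit$model)^2)
}

#' Akaike information criterion of an ML fit
#'
#' `AIC = -2 lnL + 2k`, with k counting fixed effects plus variance
#' components (random intercepts and the residual). Errors on REML fits:
#' the ladder is refit by maximum likelihood before any likelihood
#' comparison.
#'
#' @param fit A `growthFit` fitted with `method = "ML"`.
#' @return AIC value.
#' @export
aicML <- function(fit) {
  if (fit$method != "ML")
    stop("aicML: model comparison needs a maximum-likelihood fit; ",
         "refit with method = 'ML'", call. = FALSE)
  ll <- as.numeric(stats::logLik(fit$model))
  k <- nParams(fit)
  -2 * ll + 2 * k
}

nParams <- function(fit) {
  length(lme4::fixef(fit$model)) + length(fit$spec$random) + 1L
}

#' Likelihood-ratio test between nested ML fits
#'
#' `chi^2 = 2 (lnL_big - lnL_small)` clipped at zero, with degrees of
#' freedom the difference in parameter counts and the p-value from the
#' chi-square upper tail (no boundary correction).
#'
#' @param fit_small,fit_big Nested `growthFit`s, both ML, fitted to the
#'   same rows.
#' @return data.frame with `chi2`, `df`, `p`.
#' @export
lrtGrowth <- function(fit_small, fit_big) {
  if (fit_small$method != "ML" || fit_big$method != "ML")
    stop("lrtGrowth: both fits must be maximum likelihood", call. = FALSE)
  if (!isNested(fit_small$spec, fit_big$spec))
    stop("lrtGrowth: '", fit_small$spec$name, "' is not nested in '",
         fit_big$spec$name, "'", call. = FALSE)
  if (stats::nobs(fit_small$model) != stats::nobs(fit_big$model))
    stop("lrtGrowth: fits use different numbers of rows", call. = FALSE)
  chi2 <- max(0, 2 * (as.numeric(stats::logLik(fit_big$model)) -
                        as.numeric(stats::logLik(fit_small$model))))
  df <- nParams(fit_big) - nParams(fit_small)
  data.frame(chi2 = chi2, df = df,
             p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' Marginal and conditional pseudo-R-squared
#'
#' Variance-partition R^2 for Gaussian mixed models: with `varF` the
#' population variance of the fixed-effect predictions over the estimation
#' sample and `varR` the summed random-intercept variances,
#' `marginal = varF / (varF + varR + varE)` and
#' `conditional = (varF + varR) / (varF + varR + varE)`.
#'
#' @param fit A `growthFit`.
#' @return Named vector `c(marginal, conditional)`; conditional >= marginal
#'   always.
#' @export
pseudoR2 <- function(fit) {
  X <- stats::model.matrix(fit$model)
  eta <- as.vector(X %*% lme4::fixef(fit$model))
  varF <- mean((eta - mean(eta))^2)
  vc <- varianceComponents(fit)
  varR <- sum(vc[setdiff(names(vc), "resid")])
  tot <- varF + varR + vc[["resid"]]
  c(marginal = varF / tot, conditional = (varF + varR) / tot)
}

#' Fit the full model ladder
#'
#' Fits every specification in `specs` to the complete-case analysis table
#' (rows missing any predictor used anywhere in the ladder are dropped
#' once, so likelihoods are comparable).
#'
#' @param data Standardized analysis table.
#' @param specs List of `modelSpec`s (default [modelLadder()]).
#' @param method "REML" or "ML".
#' @param response Response column.
#' @return Named list of `growthFit`s.
#' @export
fitLadder <- function(data, specs = modelLadder(), method = "REML",
                      response = "rgr") {
  vars <- unique(unlist(lapply(specs, function(s)
    all.vars(specFormula(s, response = response)))))
  data <- data[stats::complete.cases(data[, intersect(vars, names(data))]), ]
  lapply(specs, function(s) fitGrowthModel(data, s, method = method,
                                           response = response))
}

#' Model-comparison table for the ladder
#'
#' Assembles, per model: ML AIC, delta-AIC relative to the base, the
#' genus-intercepts and the no-genus-moisture models, and marginal /
#' conditional pseudo-R^2 from the matching REML fits.
#'
#' @param fits_ml Named list of ML `growthFit`s (one per ladder member).
#' @param fits_reml Optional matching REML fits for the R^2 columns;
#'   defaults to using `fits_ml`.
#' @return data.frame, one row per model.
#' @export
comparisonTable <- function(fits_ml, fits_reml = fits_ml) {
  aics <- vapply(fits_ml, aicML, numeric(1))
  r2 <- t(vapply(fits_reml, pseudoR2, numeric(2)))
  ref <- function(nm) if (nm %in% names(aics)) aics - aics[[nm]] else NA_real_
  out <- data.frame(
    model = names(fits_ml),
    AIC = aics,
    dAIC_base = ref("base"),
    dAIC_genus_intercepts = ref("genus_intercepts"),
    dAIC_no_genus_moisture = ref("no_genus_moisture"),
    marginal_r2 = r2[, "marginal"],
    conditional_r2 = r2[, "conditional"],
    row.names = NULL)
  out
}
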