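#' One-sample t-test against a null mean
#'
#' Classical one-sample t-test of a vector of per-meal statistics
#' (typically adjusted-residual z-scores) against `mu0`. Missing values are
#' dropped, so the degrees of freedom shrink with the number of meals in
#' which the statistic was estimable — rare caregiver categories naturally
#' get smaller df.
#'
#' @param values numeric vector (NAs allowed).
#' @param mu0 null mean (default 0).
#' @return list of class `t_test_result`: `mean`, `t`, `df`, `p`
#'   (two-sided), `n` (values used).
#' @export
one_sample_t <- function(values, mu0 = 0) {
  x <- values[!is.na(values)]
  if (length(x) < 2) {
    stop("one_sample_t needs at least 2 non-missing values", call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("one_sample_t undefined: values have zero variance", call. = FALSE)
  }
  tt <- stats::t.test(x, mu = mu0, alternative = "two.sided")
  structure(
    list(mean = unname(tt$estimate), t = unname(tt$statistic),
         df = unname(tt$parameter), p = tt$p.value, n = length(x)),
    class = "t_test_result"
  )
}

#' @export
print.t_test_result <- function(x, ...) {
  cat(sprintf("<t_test_result> mean = %.3f, t(%d) = %.2f, p = %.4g (n = %d)\n",
              x$mean, x$df, x$t, x$p, x$n))
  invisible(x)
}

#' Test a developmental-period effect with a linear mixed-effects model
#'
#' Fits `value ~ period` with a random intercept and random period slope
#' per toddler (`nlme::lme`), the standard model for a small longitudinal
#' dyad design. The period effect is reported as a conditional F-test with
#' containment denominator degrees of freedom.
#'
#' Session-to-session variability often differs between children, and
#' `variance_strata = TRUE` adds a separate residual variance per toddler
#' (`varIdent`). It is off by default: with only a handful of meals per
#' toddler the per-stratum variances are estimated from very few residuals,
#' which makes the period F-test anti-conservative (empirical size near 0.10
#' at nominal 0.05 in null simulations at the reference design of 6 toddlers
#' x 6 meals), whereas the homoscedastic model holds its nominal size.
#' Enable it for larger designs or to mirror analyses that used variance
#' strata.
#'
#' When the requested model cannot be estimated on a given dataset, the
#' model is simplified stepwise — drop the variance strata, then the random
#' slope, then fall back to ordinary least squares — and the step used is
#' recorded in the result instead of raising an error.
#'
#' @param data data frame with columns `value` (numeric response: a
#'   frequency, proportion or z-score per session), `period`, `toddler_id`.
#'   Rows with missing `value` are dropped.
#' @param response label for the response, carried into the result.
#' @param variance_strata if `TRUE`, model a separate residual variance per
#'   toddler (see above).
#' @return list of class `period_model_fit`: `response`, `estimate` (fixed
#'   period effect, second period minus first), `se`, `F`, `num_df`,
#'   `den_df`, `p`, `random_variances` (intercept/slope variances and their
#'   correlation, where estimated), `variance_strata` (relative residual SD
#'   per toddler, where estimated), `model` (one of `"lme_varident"`,
#'   `"lme_homoscedastic"`, `"lme_intercept_only"`, `"ols"`,
#'   `"degenerate"`), `converged`, `n`, `note`.
#' @export
fit_period_model <- function(data, response = "value",
                             variance_strata = FALSE) {
  stopifnot(all(c("value", "period", "toddler_id") %in% names(data)))
  df <- data[!is.na(data$value), c("value", "period", "toddler_id")]
  df$period <- factor(df$period, levels = intersect(period_levels(),
                                                    unique(df$period)))
  df$toddler_id <- factor(df$toddler_id)
  if (nlevels(df$period) < 2) {
    stop("period effect needs data from both periods", call. = FALSE)
  }
  if (nlevels(df$toddler_id) < 2) {
    stop("period model needs at least 2 toddlers", call. = FALSE)
  }
  per_cell <- table(df$toddler_id, df$period)
  if (stats::sd(df$value) == 0 || any(colSums(per_cell > 0) < 2)) {
    return(degenerate_period_fit(response, df,
                                 "constant response or too few toddlers per period"))
  }

  ctrl <- nlme::lmeControl(maxIter = 200, msMaxIter = 200, niterEM = 50,
                           opt = "optim", returnObject = FALSE)
  attempts <- list(
    lme_varident = function() nlme::lme(
      value ~ period, random = ~ 1 + period | toddler_id,
      weights = nlme::varIdent(form = ~ 1 | toddler_id),
      data = df, method = "REML", control = ctrl),
    lme_homoscedastic = function() nlme::lme(
      value ~ period, random = ~ 1 + period | toddler_id,
      data = df, method = "REML", control = ctrl),
    lme_intercept_only = function() nlme::lme(
      value ~ period, random = ~ 1 | toddler_id,
      data = df, method = "REML", control = ctrl)
  )
  if (!variance_strata) attempts <- attempts[-1]
  for (model_name in names(attempts)) {
    fit <- tryCatch(suppressWarnings(attempts[[model_name]]()),
                    error = function(e) NULL)
    if (!is.null(fit)) {
      return(extract_period_fit(fit, model_name, response, df))
    }
  }
  ols_period_fit(response, df)
}

# internal: pull the period row out of a converged lme fit
extract_period_fit <- function(fit, model_name, response, df) {
  an <- stats::anova(fit)
  row <- grep("^period", rownames(an))
  tt <- summary(fit)$tTable
  trow <- grep("^period", rownames(tt))
  vc <- nlme::VarCorr(fit)
  rv <- list(intercept = suppressWarnings(as.numeric(vc["(Intercept)", "Variance"])))
  srow <- grep("^period", rownames(vc))
  if (length(srow) == 1) {
    rv$slope <- suppressWarnings(as.numeric(vc[srow, "Variance"]))
    corr_col <- which(colnames(vc) == "Corr")
    if (length(corr_col) == 1) {
      rv$correlation <- suppressWarnings(as.numeric(vc[srow, corr_col]))
    }
  }
  strata <- NULL
  if (!is.null(fit$modelStruct$varStruct)) {
    strata <- stats::coef(fit$modelStruct$varStruct,
                          unconstrained = FALSE, allCoef = TRUE)
  }
  structure(
    list(response = response,
         estimate = unname(tt[trow, "Value"]),
         se = unname(tt[trow, "Std.Error"]),
         F = unname(an[row, "F-value"]),
         num_df = unname(an[row, "numDF"]),
         den_df = unname(an[row, "denDF"]),
         p = unname(an[row, "p-value"]),
         random_variances = rv,
         variance_strata = strata,
         model = model_name, converged = TRUE,
         n = nrow(df), note = ""),
    class = "period_model_fit"
  )
}

# internal: ordinary least squares fallback
ols_period_fit <- function(response, df) {
  fit <- stats::lm(value ~ period, data = df)
  an <- stats::anova(fit)
  co <- summary(fit)$coefficients
  trow <- grep("^period", rownames(co))
  structure(
    list(response = response,
         estimate = unname(co[trow, "Estimate"]),
         se = unname(co[trow, "Std. Error"]),
         F = an["period", "F value"],
         num_df = an["period", "Df"],
         den_df = an["Residuals", "Df"],
         p = an["period", "Pr(>F)"],
         random_variances = NULL, variance_strata = NULL,
         model = "ols", converged = TRUE, n = nrow(df),
         note = "mixed model inestimable; ordinary least squares used"),
    class = "period_model_fit"
  )
}

# internal: flagged non-result for degenerate inputs
degenerate_period_fit <- function(response, df, note) {
  structure(
    list(response = response, estimate = if (nrow(df) > 0) 0 else NA_real_,
         se = NA_real_, F = NA_real_, num_df = NA_integer_,
         den_df = NA_integer_, p = NA_real_,
         random_variances = NULL, variance_strata = NULL,
         model = "degenerate", converged = FALSE, n = nrow(df), note = note),
    class = "period_model_fit"
  )
}

#' @export
print.period_model_fit <- function(x, ...) {
  if (x$model == "degenerate") {
    cat(sprintf("<period_model_fit> %s: degenerate (%s)\n", x$response, x$note))
  } else {
    cat(sprintf(
      "<period_model_fit> %s: estimate %.3f (SE %.3f), F(%d, %d) = %.2f, p = %.4g [%s]\n",
      x$response, x$estimate, x$se, x$num_df, x$den_df, x$F, x$p, x$model))
  }
  invisible(x)
}

#' Pooled category association tests
#'
#' Pools the per-meal adjusted residuals of all sessions (both periods) and
#' tests, per caregiver category, whether the mean z differs from zero by a
#' two-sided one-sample t-test. No multiple-testing correction is applied by
#' default (each category is reported at `alpha` per test); Holm adjustment
#' across the seven categories is available via `adjust`.
#'
#' @param ztab a [study_zscores()] table.
#' @param alpha two-sided significance level for the marker column.
#' @param adjust `"none"` (default) or `"holm"`.
#' @return tibble, one row per analysis category: `category`, `n` (meals
#'   with an estimable z), `mean_z`, `t`, `df`, `p`, `significant`.
#' @export
summarize_category_tests <- function(ztab, alpha = 0.05,
                                     adjust = c("none", "holm")) {
  adjust <- match.arg(adjust)
  rows <- lapply(analysis_categories(), function(cat) {
    z <- ztab$z[ztab$category == cat]
    z <- z[!is.na(z)]
    if (length(z) < 2 || stats::sd(z) == 0) {
      return(tibble::tibble(category = cat, n = length(z),
                            mean_z = if (length(z)) mean(z) else NA_real_,
                            t = NA_real_, df = NA_integer_, p = NA_real_))
    }
    tt <- one_sample_t(z)
    tibble::tibble(category = cat, n = tt$n, mean_z = tt$mean,
                   t = tt$t, df = tt$df, p = tt$p)
  })
  out <- do.call(rbind, rows)
  p_marked <- if (adjust == "holm") stats::p.adjust(out$p, "holm") else out$p
  out$significant <- !is.na(p_marked) & p_marked < alpha
  out
}

#' Per-category period contrasts on adjusted residuals
#'
#' Applies [fit_period_model()] to the per-meal z-scores of each caregiver
#' category in turn, testing whether the association between that category
#' and toddler pointing changed between the two periods. Categories with
#' fewer than two estimable meals in either period are returned as flagged
#' degenerate fits rather than dropped silently.
#'
#' @inheritParams summarize_category_tests
#' @inheritParams fit_period_model
#' @return named list of `period_model_fit`, one per analysis category.
#' @export
period_contrast_per_category <- function(ztab, variance_strata = FALSE) {
  fits <- lapply(analysis_categories(), function(cat) {
    sub <- ztab[ztab$category == cat & !is.na(ztab$z), , drop = FALSE]
    enough <- nrow(sub) > 0 &&
      all(table(factor(sub$period, levels = period_levels())) >= 2)
    if (!enough) {
      return(degenerate_period_fit(
        paste0("z_", cat), data.frame(value = numeric()),
        "fewer than 2 estimable meals in a period"))
    }
    df <- data.frame(value = sub$z, period = sub$period,
                     toddler_id = sub$toddler_id)
    tryCatch(
      fit_period_model(df, response = paste0("z_", cat),
                       variance_strata = variance_strata),
      error = function(e) degenerate_period_fit(paste0("z_", cat), df,
                                                conditionMessage(e))
    )
  })
  stats::setNames(fits, analysis_categories())
}

#' @rdname period_contrast_per_category
#' @param fits result of `period_contrast_per_category()`.
#' @return `period_contrast_table()` flattens the fits into a tibble.
#' @export
period_contrast_table <- function(fits) {
  rows <- lapply(names(fits), function(cat) {
    f <- fits[[cat]]
    tibble::tibble(
      category = cat, estimate = f$estimate, se = f$se, F = f$F,
      num_df = f$num_df, den_df = f$den_df, p = f$p, model = f$model,
      converged = f$converged, n = f$n, note = f$note
    )
  })
  do.call(rbind, rows)
}
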