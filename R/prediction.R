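#' Fit an ordinary least-squares model for one delta outcome
#'
#' Least-squares fit of a delta gait variable on clinical covariates, with
#' classical standard errors, two-sided t p-values, adjusted R-squared and
#' the overall F test — the shape of a clinical prediction table block.
#'
#' @param data data.frame containing the outcome and predictors.
#' @param outcome name of the outcome column.
#' @param predictors character vector of predictor column names.
#' @return object of class `fitted_gait_model`: `coefficients` (data.frame
#'   term/B/SE/p), `adjusted_r2`, `r2`, `f_stat`, `model_p`, `n`,
#'   `outcome`, `lm` (the underlying `lm` fit).
#' @export
fit_ols <- function(data, outcome, predictors) {
  if (!outcome %in% names(data)) stop("outcome '", outcome, "' not in data")
  miss <- setdiff(predictors, names(data))
  if (length(miss)) stop("predictors not in data: ", paste(miss, collapse = ", "))
  d <- data[complete.cases(data[, c(outcome, predictors), drop = FALSE]), ]
  n <- nrow(d)
  if (n <= length(predictors) + 1)
    stop("need n > p + 1 observations (n = ", n, ", p = ", length(predictors), ")")
  fit <- lm(stats::reformulate(predictors, response = outcome), data = d)
  if (fit$rank < length(predictors) + 1) {
    bad <- names(coef(fit))[is.na(coef(fit))]
    stop("rank-deficient design; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  coefs <- data.frame(term = rownames(ct), B = ct[, 1], SE = ct[, 2],
                      p = ct[, 4], row.names = NULL)
  fstat <- sm$fstatistic
  model_p <- if (is.null(fstat)) NA_real_ else
    pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  structure(list(coefficients = coefs, adjusted_r2 = sm$adj.r.squared,
                 r2 = sm$r.squared,
                 f_stat = if (is.null(fstat)) NA_real_ else unname(fstat[1]),
                 model_p = unname(model_p), n = n, outcome = outcome,
                 lm = fit),
            class = "fitted_gait_model")
}

#' @export
print.fitted_gait_model <- function(x, ...) {
  cat("<fitted_gait_model>", x$outcome, sprintf("(n = %d)\n", x$n))
  print(transform(x$coefficients, B = signif(B, 4), SE = signif(SE, 4),
                  p = signif(p, 3)), row.names = FALSE)
  cat(sprintf("  adjusted R2 = %.3f, F = %.3f, model p = %.4g\n",
              x$adjusted_r2, x$f_stat, x$model_p))
  invisible(x)
}

#' Backward-selection multiple regression
#'
#' Starting from the full candidate set, iteratively refits after dropping
#' the predictor with the largest p-value above `removal_alpha`, until every
#' retained predictor has p <= `removal_alpha` or only the intercept and the
#' protected baseline covariate remain. The baseline value of the outcome's
#' own variable is never dropped. Ties in the removal p-value are broken by
#' lexicographic predictor name, making the procedure invariant to predictor
#' ordering.
#'
#' @param data data.frame with outcome and candidate predictors.
#' @param outcome outcome column name.
#' @param candidates character vector of candidate predictor names.
#' @param baseline name of the protected baseline covariate; must be among
#'   `candidates`.
#' @param removal_alpha removal threshold (default 0.10).
#' @return a `fitted_gait_model` for the final model, with an extra element
#'   `dropped` (character, in removal order).
#' @export
backward_eliminate <- function(data, outcome, candidates, baseline,
                               removal_alpha = 0.10) {
  if (!baseline %in% candidates)
    stop("the baseline covariate must be among the candidates")
  current <- candidates
  dropped <- character(0)
  repeat {
    fit <- fit_ols(data, outcome, current)
    cf <- fit$coefficients
    cf <- cf[cf$term != "(Intercept)" & cf$term != baseline, , drop = FALSE]
    if (!nrow(cf)) break
    worst_p <- max(cf$p)
    if (worst_p <= removal_alpha) break
    worst <- sort(cf$term[cf$p == worst_p])[1]
    dropped <- c(dropped, worst)
    current <- setdiff(current, worst)
  }
  fit$dropped <- dropped
  fit
}

#' Regression validity diagnostics
#'
#' The standard validity checks of a multiple-regression analysis:
#' Durbin-Watson statistic (independence of residuals), variance inflation
#' factors (multicollinearity), Shapiro-Wilk on residuals (normality),
#' Breusch-Pagan test (homoscedasticity), and studentized residuals beyond
#' +/- 3 (outliers).
#'
#' @param model a `fitted_gait_model`.
#' @return list of class `gait_model_diagnostics`: `durbin_watson`, `vif`
#'   (named, `NA` for single-predictor models), `residual_normality_p`,
#'   `heteroscedasticity_p`, `outlier_rows` (integer indices).
#' @export
validate_model <- function(model) {
  fit <- model$lm
  dw <- lmtest::dwtest(fit)
  bp <- lmtest::bptest(fit)
  np <- shapiro.test(residuals(fit))$p.value
  nterms <- length(attr(stats::terms(fit), "term.labels"))
  vifs <- if (nterms >= 2) car::vif(fit) else
    setNames(rep(NA_real_, nterms), attr(stats::terms(fit), "term.labels"))
  stud <- rstudent(fit)
  structure(list(durbin_watson = unname(dw$statistic), vif = vifs,
                 residual_normality_p = np,
                 heteroscedasticity_p = bp$p.value,
                 outlier_rows = which(abs(stud) > 3)),
            class = "gait_model_diagnostics")
}

#' @export
print.gait_model_diagnostics <- function(x, ...) {
  cat(sprintf("<gait_model_diagnostics> DW %.2f, residual normality p %.3f, BP p %.3f\n",
              x$durbin_watson, x$residual_normality_p, x$heteroscedasticity_p))
  if (length(x$vif) && !all(is.na(x$vif)))
    cat("  VIF:", paste(sprintf("%s %.2f", names(x$vif), x$vif), collapse = ", "), "\n")
  cat("  outliers (|studentized| > 3):",
      if (length(x$outlier_rows)) paste(x$outlier_rows, collapse = ", ") else "none", "\n")
  invisible(x)
}
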