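#' Speed-match control trials to the patient group
#'
#' Keeps, per session, the control trials whose gait speed falls in the
#' closed interval `[patient mean - SD, patient mean + SD]`, removing speed
#' as a confound before case-control comparison. A control subject with no
#' surviving trials is excluded from matched comparisons (the caller logs
#' this via the returned indices).
#'
#' @param control_speeds numeric vector of per-trial control speeds (m/s).
#' @param patient_speed_mean,patient_speed_sd patient-group speed moments;
#'   the SD must be positive.
#' @return logical vector: `TRUE` for retained trials.
#' @examples
#' match_speed_trials(c(0.6, 0.8, 1.2), 0.777, 0.305)  # TRUE TRUE FALSE
#' @export
match_speed_trials <- function(control_speeds, patient_speed_mean,
                               patient_speed_sd) {
  if (!is.finite(patient_speed_sd) || patient_speed_sd <= 0)
    stop("patient_speed_sd must be positive")
  control_speeds >= patient_speed_mean - patient_speed_sd &
    control_speeds <= patient_speed_mean + patient_speed_sd
}

#' Percent change (delta) between sessions
#'
#' `100 * (value_10week - value_baseline) / value_baseline`, the signed
#' percent change from baseline to the 10-week evaluation.
#'
#' @param value_baseline baseline value (non-zero).
#' @param value_10week follow-up value.
#' @return percent change.
#' @examples
#' delta_pct(0.777, 0.864)  # +11.2
#' @export
delta_pct <- function(value_baseline, value_10week) {
  if (any(value_baseline == 0)) stop("baseline value must be non-zero")
  100 * (value_10week - value_baseline) / value_baseline
}

#' Pooled two-sample t statistic from printed moments
#'
#' Closed-form Student (pooled-variance) t from group means, SDs and sizes —
#' the statistic a two-sample comparison table prints, recomputable from the
#' table alone.
#'
#' @param m1,s1,n1,m2,s2,n2 means, SDs and sizes of the two groups.
#' @return list with `t`, `df`, `p` (two-sided), `pooled_sd`.
#' @export
pooled_t_from_moments <- function(m1, s1, n1, m2, s2, n2) {
  sp <- sqrt(((n1 - 1) * s1^2 + (n2 - 1) * s2^2) / (n1 + n2 - 2))
  tt <- (m1 - m2) / (sp * sqrt(1 / n1 + 1 / n2))
  df <- n1 + n2 - 2
  list(t = tt, df = df, p = 2 * pt(-abs(tt), df), pooled_sd = sp)
}

#' Cohen's d effect size
#'
#' Unpaired: absolute mean difference over the pooled SD. Paired: absolute
#' mean of the differences over the SD of the differences. The absolute-value
#' convention matches effect-size tables that report all d >= 0.
#'
#' @param sample1,sample2 numeric samples (paired: equal length).
#' @param paired logical.
#' @return non-negative effect size.
#' @export
cohen_d <- function(sample1, sample2, paired = FALSE) {
  if (paired) {
    d <- sample1 - sample2
    s <- sd(d)
    if (s == 0) stop("zero SD of differences")
    abs(mean(d)) / s
  } else {
    n1 <- length(sample1); n2 <- length(sample2)
    sp <- sqrt(((n1 - 1) * var(sample1) + (n2 - 1) * var(sample2)) /
                 (n1 + n2 - 2))
    if (sp == 0) stop("zero pooled SD")
    abs(mean(sample1) - mean(sample2)) / sp
  }
}

#' Normality-gated two-sample comparison
#'
#' The comparison procedure applied to every gait variable: Shapiro-Wilk on
#' each sample (on the paired differences when `paired = TRUE`) at
#' `normality_alpha`; if normality is not rejected, Student's pooled t-test
#' (or paired t-test), otherwise Mann-Whitney U (or Wilcoxon signed-rank).
#' Cohen's d is reported alongside.
#'
#' @param sample1,sample2 numeric samples, n >= 3 each.
#' @param paired logical.
#' @param normality_alpha gate level for the Shapiro-Wilk test (default 0.05).
#' @return list of class `comparison_result`: `test`, `statistic`, `p_value`,
#'   `cohen_d`, `n1`, `n2`, `normality_p` (length 2 or 1).
#' @export
compare_groups <- function(sample1, sample2, paired = FALSE,
                           normality_alpha = 0.05) {
  if (length(sample1) < 3 || length(sample2) < 3)
    stop("need at least 3 observations per sample")
  if (paired && length(sample1) != length(sample2))
    stop("paired samples must have equal length")
  if (var(sample1) == 0 && var(sample2) == 0)
    stop("zero variance in both samples")
  if (paired) {
    d <- sample1 - sample2
    norm_p <- shapiro.test(d)$p.value
    normal <- norm_p > normality_alpha
    res <- if (normal) t.test(sample1, sample2, paired = TRUE)
           else suppressWarnings(wilcox.test(sample1, sample2, paired = TRUE,
                                             exact = length(d) < 50))
    test <- if (normal) "paired-t" else "Wilcoxon"
  } else {
    norm_p <- c(shapiro.test(sample1)$p.value, shapiro.test(sample2)$p.value)
    normal <- all(norm_p > normality_alpha)
    res <- if (normal) t.test(sample1, sample2, var.equal = TRUE)
           else suppressWarnings(wilcox.test(sample1, sample2,
                 exact = length(sample1) + length(sample2) < 50))
    test <- if (normal) "pooled-t" else "Mann-Whitney"
  }
  structure(list(test = test, statistic = unname(res$statistic),
                 p_value = res$p.value,
                 cohen_d = cohen_d(sample1, sample2, paired = paired),
                 n1 = length(sample1), n2 = length(sample2),
                 normality_p = norm_p),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic %.3f, p %.4g, d %.3f (n = %d/%d)\n",
              x$test, x$statistic, x$p_value, x$cohen_d, x$n1, x$n2))
  invisible(x)
}

#' Classify a patient's change as improvement
#'
#' A gait parameter improves when the follow-up value moves strictly closer
#' to the healthy-control mean than the baseline value was, whatever the
#' sign of the change. Equal distances (including a baseline already at the
#' control mean) are conservatively classified as not improved.
#'
#' @param value_baseline,value_10week patient values at the two sessions.
#' @param control_mean control-group mean for the variable.
#' @return `TRUE` if improved.
#' @export
classify_improvement <- function(value_baseline, value_10week, control_mean) {
  d_base <- abs(value_baseline - control_mean)
  d_fup <- abs(value_10week - control_mean)
  # strict inequality with a relative guard so numerically equal distances
  # (ties) classify as not improved
  tol <- 1e-9 * pmax(1, abs(control_mean))
  d_fup < d_base - tol
}

#' Chi-square test of the improved proportion
#'
#' One-degree-of-freedom goodness-of-fit of the improved / not-improved
#' split against an even (50/50) null, without continuity correction.
#'
#' @param n_improved,n_total counts.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
improvement_chi_square <- function(n_improved, n_total) {
  if (n_improved < 0 || n_improved > n_total) stop("invalid counts")
  res <- chisq.test(c(n_improved, n_total - n_improved), correct = FALSE)
  list(statistic = unname(res$statistic), p_value = res$p.value, df = 1)
}

#' Normality-gated bivariate correlation
#'
#' Pearson correlation when both variables pass the Shapiro-Wilk gate,
#' Spearman rank correlation otherwise.
#'
#' @param x,y numeric vectors.
#' @param normality_alpha gate level (default 0.05).
#' @return list with `method`, `estimate`, `p_value`.
#' @export
bivariate_correlation <- function(x, y, normality_alpha = 0.05) {
  ok <- complete.cases(x, y); x <- x[ok]; y <- y[ok]
  normal <- shapiro.test(x)$p.value > normality_alpha &&
            shapiro.test(y)$p.value > normality_alpha
  method <- if (normal) "pearson" else "spearman"
  res <- suppressWarnings(cor.test(x, y, method = method))
  list(method = method, estimate = unname(res$estimate), p_value = res$p.value)
}

#' A priori sample size for a paired t-test
#'
#' Smallest number of pairs whose noncentral-t power reaches the target for
#' a two-sided (or one-sided) paired t-test at effect size `d` (mean
#' difference in SD-of-differences units).
#'
#' @param effect_size_d standardized effect size (> 0).
#' @param power target power in (0, 1) (default 0.80).
#' @param alpha significance level (default 0.05).
#' @param two_sided logical (default TRUE).
#' @return integer sample size (number of pairs).
#' @examples
#' paired_power_sample_size(0.5)  # 34
#' @export
paired_power_sample_size <- function(effect_size_d, power = 0.80,
                                     alpha = 0.05, two_sided = TRUE) {
  if (effect_size_d == 0) stop("effect size must be non-zero")
  if (power <= 0 || power >= 1) stop("power must be in (0, 1)")
  d <- abs(effect_size_d)
  achieved <- function(n) {
    df <- n - 1; ncp <- d * sqrt(n)
    if (two_sided) {
      tc <- qt(1 - alpha / 2, df)
      1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
    } else {
      1 - pt(qt(1 - alpha, df), df, ncp)
    }
  }
  n <- 2
  while (achieved(n) < power) {
    n <- n + 1
    if (n > 1e6) stop("sample size search did not converge")
  }
  n
}
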