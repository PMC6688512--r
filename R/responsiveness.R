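#' Anchor classification: did a patient normalize a parameter?
#'
#' The external anchor for responsiveness analysis: a patient normalizes a
#' variable when (a) the follow-up value moved strictly closer to the
#' control mean than baseline (the improvement rule of
#' [classify_improvement()]), and (b) the follow-up value lies on the
#' healthy side of a band around the control mean: below
#' `control_mean + k * control_sd` for lower-is-better variables, above
#' `control_mean - k * control_sd` for higher-is-better ones. "Reached
#' control values" is operationalized by the band; `k` is configurable
#' (default 1 control SD).
#'
#' @param value_baseline,value_10week patient values at the two sessions.
#' @param control_mean,control_sd control-group moments for the variable.
#' @param direction `"lower"` if smaller values are healthier (e.g. spatial
#'   asymmetry), `"higher"` otherwise (e.g. trunk rotation RoM).
#' @param k width of the normalization band in control SDs (default 1).
#' @return logical: normalized or not.
#' @export
anchor_classify <- function(value_baseline, value_10week, control_mean,
                            control_sd, direction = c("lower", "higher"),
                            k = 1) {
  direction <- match.arg(direction)
  improved <- classify_improvement(value_baseline, value_10week, control_mean)
  reached <- if (direction == "lower")
    value_10week <= control_mean + k * control_sd
  else
    value_10week >= control_mean - k * control_sd
  improved & reached
}

#' Empirical ROC curve and AUC with DeLong confidence interval
#'
#' Empirical ROC of a continuous score against a binary anchor label. The
#' AUC is the Mann-Whitney concordance probability
#' (concordant pairs + half ties) / (all positive-negative pairs). The
#' orientation is chosen so AUC >= 0.5 and reported: `"higher"` means larger
#' scores indicate the positive class. The confidence interval is DeLong's
#' (placement-value variance, logit-free normal interval truncated to
#' \[0, 1\]); an exact binomial-free alternative is out of scope.
#'
#' @param score numeric scores (e.g. per-patient percent changes).
#' @param label logical or 0/1 anchor labels; both classes must be present.
#' @param conf_level confidence level for the AUC interval (default 0.95).
#' @return list of class `roc_result`: `auc`, `ci` (low, high),
#'   `orientation`, `points` (data.frame threshold/se/sp of the empirical
#'   curve, oriented), `score`, `label`.
#' @export
roc_auc <- function(score, label, conf_level = 0.95) {
  label <- as.logical(label)
  ok <- complete.cases(score, label); score <- score[ok]; label <- label[ok]
  n1 <- sum(label); n0 <- sum(!label)
  if (n1 == 0 || n0 == 0) stop("both classes must be non-empty")
  auc_of <- function(s) {
    r <- rank(s, ties.method = "average")
    (sum(r[label]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  a_raw <- auc_of(score)
  orientation <- if (a_raw >= 0.5) "higher" else "lower"
  s <- if (orientation == "higher") score else -score
  auc <- auc_of(s)
  x <- s[label]; y <- s[!label]
  # DeLong placement values
  psi <- function(a, b) (a > b) + 0.5 * (a == b)
  v10 <- vapply(x, function(xi) mean(psi(xi, y)), numeric(1))
  v01 <- vapply(y, function(yj) mean(psi(x, yj)), numeric(1))
  va <- var(v10) / n1 + var(v01) / n0
  z <- qnorm(1 - (1 - conf_level) / 2)
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * z * sqrt(va)))
  # empirical curve over candidate thresholds (midpoints + extremes)
  thr <- roc_thresholds(s)
  pts <- data.frame(
    threshold = thr,
    se = vapply(thr, function(th) mean(x > th), numeric(1)),
    sp = vapply(thr, function(th) mean(y <= th), numeric(1)))
  structure(list(auc = auc, ci = ci, orientation = orientation,
                 points = pts, score = s, label = label),
            class = "roc_result")
}

# candidate cut-offs: midpoints between sorted distinct scores plus outer
# sentinels (MedCalc-style "criterion > t" thresholds)
roc_thresholds <- function(s) {
  u <- sort(unique(s))
  c(u[1] - 1, (head(u, -1) + tail(u, -1)) / 2, u[length(u)] + 1)
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result> AUC %.3f (%.3f-%.3f), orientation: %s scores positive\n",
              x$auc, x$ci[1], x$ci[2], x$orientation))
  invisible(x)
}

#' Optimal MCID cut-off from a ROC curve
#'
#' Selects the threshold minimizing `(1 - Se)^2 + (1 - Sp)^2` over the
#' candidate cut-offs (midpoints between sorted distinct scores). Ties are
#' broken toward higher sensitivity, then toward the higher threshold. The
#' cut-off is reported on the oriented score scale: a positive
#' classification is `score > cutoff` in the direction indicating the
#' positive class.
#'
#' @param roc a `roc_result` from [roc_auc()].
#' @return list with `cutoff`, `se`, `sp` (proportions), `criterion`
#'   (the minimized sum of squares).
#' @export
mcid_cutoff <- function(roc) {
  pts <- roc$points
  crit <- (1 - pts$se)^2 + (1 - pts$sp)^2
  best <- which(crit == min(crit))
  if (length(best) > 1) {
    best <- best[pts$se[best] == max(pts$se[best])]
    best <- best[which.max(pts$threshold[best])]
  }
  list(cutoff = pts$threshold[best], se = pts$se[best], sp = pts$sp[best],
       criterion = crit[best])
}

#' Likelihood ratios and predictive values
#'
#' Standard diagnostic arithmetic from sensitivity, specificity and
#' prevalence: `LR+ = Se / (1 - Sp)`, `LR- = (1 - Se) / Sp`, and the
#' positive/negative predictive values by Bayes' rule at the supplied
#' prevalence. With `Sp = 1` the positive likelihood ratio is reported as
#' `Inf`.
#'
#' @param se,sp sensitivity and specificity as proportions in (0, 1\].
#' @param prevalence pre-test probability of the positive class in (0, 1).
#' @return list with `lr_pos`, `lr_neg`, `pv_pos`, `pv_neg` (proportions).
#' @examples
#' diagnostic_stats(0.9474, 0.8824, 19/36)  # LR+ 8.06, PV+ 0.90
#' @export
diagnostic_stats <- function(se, sp, prevalence) {
  if (se <= 0 || se > 1 || sp <= 0 || sp > 1)
    stop("se and sp must be proportions in (0, 1]")
  if (prevalence <= 0 || prevalence >= 1)
    stop("prevalence must be in (0, 1)")
  lr_pos <- if (sp == 1) Inf else se / (1 - sp)
  lr_neg <- (1 - se) / sp
  pv_pos <- se * prevalence / (se * prevalence + (1 - sp) * (1 - prevalence))
  pv_neg <- sp * (1 - prevalence) /
    (sp * (1 - prevalence) + (1 - se) * prevalence)
  list(lr_pos = lr_pos, lr_neg = lr_neg, pv_pos = pv_pos, pv_neg = pv_neg)
}

#' Post-test probability from a likelihood ratio
#'
#' The arithmetic behind Fagan's nomogram: pre-test odds times the
#' likelihood ratio, transformed back to a probability.
#'
#' @param lr likelihood ratio (> 0).
#' @param pretest_prob pre-test probability in (0, 1).
#' @return post-test probability.
#' @examples
#' posttest_probability(8.06, 19/36)  # ~0.90
#' @export
posttest_probability <- function(lr, pretest_prob) {
  if (lr <= 0) stop("likelihood ratio must be positive")
  if (pretest_prob <= 0 || pretest_prob >= 1)
    stop("pretest probability must be in (0, 1)")
  odds <- pretest_prob / (1 - pretest_prob) * lr
  odds / (1 + odds)
}

#' Full anchor-based MCID analysis of one delta variable
#'
#' Runs [roc_auc()], [mcid_cutoff()], [diagnostic_stats()] and
#' [posttest_probability()] for one variable's per-patient percent changes
#' against its normalization anchor, assembling the responsiveness table
#' row: AUC with CI, MCID cut-off with its direction, Se/Sp (percent), LR+,
#' LR-, PV+, PV- and post-test probabilities at the observed prevalence.
#'
#' @param deltas per-patient percent changes (Eq.-2 scale).
#' @param normalized logical anchor labels (see [anchor_classify()]).
#' @param variable variable name carried into the result.
#' @param conf_level AUC confidence level.
#' @return list of class `mcid_result`.
#' @export
mcid_analysis <- function(deltas, normalized, variable = "delta",
                          conf_level = 0.95) {
  roc <- roc_auc(deltas, normalized, conf_level = conf_level)
  cut <- mcid_cutoff(roc)
  prev <- mean(as.logical(normalized))
  ds <- diagnostic_stats(max(cut$se, 1e-12), max(cut$sp, 1e-12), prev)
  structure(list(
    variable = variable, auc = roc$auc, auc_ci_low = roc$ci[1],
    auc_ci_high = roc$ci[2], orientation = roc$orientation,
    mcid_cutoff = cut$cutoff, se_pct = 100 * cut$se, sp_pct = 100 * cut$sp,
    lr_pos = ds$lr_pos, lr_neg = ds$lr_neg,
    pv_pos = ds$pv_pos, pv_neg = ds$pv_neg,
    posttest_prob_pos = if (is.finite(ds$lr_pos))
      posttest_probability(ds$lr_pos, prev) else 1,
    posttest_prob_neg = if (ds$lr_neg > 0)
      posttest_probability(ds$lr_neg, prev) else 0,
    n_normalized = sum(as.logical(normalized)),
    n_total = length(normalized)),
    class = "mcid_result")
}

#' @export
print.mcid_result <- function(x, ...) {
  cat(sprintf("<mcid_result> %s: AUC %.3f (%.3f-%.3f)\n", x$variable,
              x$auc, x$auc_ci_low, x$auc_ci_high))
  cat(sprintf("  MCID %s > %.2f: Se %.1f%%, Sp %.1f%%, LR+ %.2f, LR- %.3f, PV+ %.1f%%, PV- %.1f%%\n",
              if (x$orientation == "lower") "(reduction)" else "",
              x$mcid_cutoff, x$se_pct, x$sp_pct, x$lr_pos, x$lr_neg,
              100 * x$pv_pos, 100 * x$pv_neg))
  cat(sprintf("  normalized %d/%d\n", x$n_normalized, x$n_total))
  invisible(x)
}
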