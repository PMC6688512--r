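# independent oracles for the ROC machinery
brute_auc <- function(score, label) {
  x <- score[label]; y <- score[!label]
  pairs <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}
brute_mcid <- function(score, label) {
  u <- sort(unique(score))
  thr <- c(u[1] - 1, (head(u, -1) + tail(u, -1)) / 2, u[length(u)] + 1)
  best <- NULL
  for (th in thr) {
    se <- mean(score[label] > th); sp <- mean(score[!label] <= th)
    cr <- (1 - se)^2 + (1 - sp)^2
    if (is.null(best) || cr < best$cr - 1e-12 ||
        (abs(cr - best$cr) <= 1e-12 &&
         (se > best$se + 1e-12 ||
          (abs(se - best$se) <= 1e-12 && th > best$th))))
      best <- list(th = th, se = se, sp = sp, cr = cr)
  }
  best
}

test_that("anchor classification combines improvement and the control band", {
  # asymmetry 20 -> 5 with control 5.5 +/- 4.7 and k = 1: normalized
  expect_true(anchor_classify(20, 5, 5.5, 4.7, "lower", k = 1))
  # worsening is never normalized, whatever the band
  expect_false(anchor_classify(20, 25, 5.5, 4.7, "lower", k = 100))
  # higher-is-better mirror (trunk rotation reaching control values)
  expect_true(anchor_classify(7, 9.5, 10.2, 3.8, "higher", k = 1))
  expect_false(anchor_classify(7, 5.5, 10.2, 3.8, "higher", k = 1))
})

test_that("the k = 0 normalized set is a subset of the k = 1 set", {
  set.seed(10)
  for (i in 1:200) {
    b <- runif(1, 5, 30); f <- runif(1, 0, 30)
    n0 <- anchor_classify(b, f, 6, 4, "lower", k = 0)
    n1 <- anchor_classify(b, f, 6, 4, "lower", k = 1)
    if (n0) expect_true(n1)
  }
})

test_that("AUC equals the brute-force concordance probability", {
  # perfectly separated scores
  r <- roc_auc(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  expect_equal(r$auc, 1)
  # 6-point toy set with ties against pair counting
  s <- c(1, 2, 2, 3, 4, 4); l <- c(FALSE, TRUE, FALSE, TRUE, FALSE, TRUE)
  r2 <- roc_auc(s, l)
  expect_equal(r2$auc, brute_auc(s, l))
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")
  # labels independent of scores: AUC near 1/2 at large n
  set.seed(11)
  r3 <- roc_auc(rnorm(4000), rbinom(4000, 1, 0.5))
  expect_lt(abs(r3$auc - 0.5), 0.04)
  expect_gte(r3$auc, 0.5)   # orientation keeps AUC above chance
})

test_that("AUC and DeLong CI agree with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(12)
  score <- c(rnorm(18, 1), rnorm(14))
  label <- rep(c(1, 0), c(18, 14))
  r <- roc_auc(score, label)
  pr <- pROC::roc(label, score, quiet = TRUE, direction = "<")
  expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-12)
  ci <- as.numeric(pROC::ci.auc(pr, method = "delong"))
  expect_equal(r$ci[1], ci[1], tolerance = 1e-8)
  expect_equal(r$ci[2], ci[3], tolerance = 1e-8)
})

test_that("the MCID cut-off matches the exhaustive-scan oracle", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(6:30, 1)
    score <- round(rnorm(n, 0, 10), sample(0:1, 1))
    label <- as.logical(rbinom(n, 1, 0.5))
    if (!any(label) || all(label)) next
    r <- roc_auc(score, label)
    got <- mcid_cutoff(r)
    want <- brute_mcid(r$score, r$label)
    expect_equal(got$cutoff, want$th)
    expect_equal(got$se, want$se)
    expect_equal(got$sp, want$sp)
  }
  # perfect separation: criterion value 0 at any separating cut-off
  r <- roc_auc(c(1, 2, 3, 11, 12, 13), c(0, 0, 0, 1, 1, 1))
  cut <- mcid_cutoff(r)
  expect_equal(cut$criterion, 0)
  expect_true(cut$cutoff > 3 && cut$cutoff < 11)
})

test_that("diagnostic statistics reproduce the printed table arithmetic", {
  # spatial asymmetry row: Se 94.74, Sp 88.24, prevalence 19/36
  d1 <- diagnostic_stats(0.9474, 0.8824, 19 / 36)
  expect_equal(d1$lr_pos, 8.05, tolerance = 0.01 / 8.05)
  expect_equal(100 * d1$pv_pos, 90.0, tolerance = 0.1 / 90)
  # trunk rotation row: Se 95, Sp 56.25, prevalence 20/36
  d2 <- diagnostic_stats(0.95, 0.5625, 20 / 36)
  expect_equal(d2$lr_pos, 2.17, tolerance = 0.01 / 2.17)
  expect_equal(100 * d2$pv_pos, 73.1, tolerance = 0.1 / 73.1)
  expect_equal(diagnostic_stats(0.9, 1, 0.5)$lr_pos, Inf)
  expect_error(diagnostic_stats(0.9, 0.8, 1.5), "prevalence")
})

test_that("predictive values rise with sensitivity and specificity", {
  set.seed(14)
  for (i in 1:50) {
    se <- runif(1, 0.05, 0.9); sp <- runif(1, 0.05, 0.9); d <- runif(1, 0.01, 0.09)
    base <- diagnostic_stats(se, sp, 0.5)$pv_pos
    expect_gt(diagnostic_stats(se + d, sp, 0.5)$pv_pos, base)
    expect_gt(diagnostic_stats(se, sp + d, 0.5)$pv_pos, base)
  }
})

test_that("post-test probability is the Fagan odds arithmetic", {
  expect_equal(posttest_probability(8.0561, 19 / 36), 0.900, tolerance = 1e-3)
  expect_equal(posttest_probability(2.1714, 20 / 36), 0.731, tolerance = 1e-3)
  expect_equal(posttest_probability(1, 0.37), 0.37)
  expect_error(posttest_probability(0, 0.5), "positive")
  expect_error(posttest_probability(2, 1), "pretest")
  # LR+ at the observed prevalence reproduces PV+
  d <- diagnostic_stats(0.9474, 0.8824, 19 / 36)
  expect_equal(posttest_probability(d$lr_pos, 19 / 36), d$pv_pos,
               tolerance = 1e-12)
})

test_that("a known normalization threshold is recovered as the MCID", {
  # normalizers reduce their asymmetry by ~40%, non-normalizers by ~10%
  # (SD 10): the separating threshold is 25, recovered within +/-20%
  cuts <- vapply(1:100, function(sd) {
    set.seed(400 + sd)
    lab <- as.logical(rbinom(36, 1, 0.52))
    reduction <- rnorm(36, ifelse(lab, 40, 10), 10)
    mcid_analysis(reduction, lab)$mcid_cutoff
  }, numeric(1))
  expect_lt(abs(mean(cuts) - 25), 5)
  expect_gt(mean(cuts > 15 & cuts < 35), 0.9)
})

test_that("the full MCID analysis row is internally consistent", {
  set.seed(15)
  lab <- as.logical(rbinom(36, 1, 0.5))
  score <- rnorm(36, ifelse(lab, 30, 5), 12)
  m <- mcid_analysis(score, lab, "toy")
  expect_equal(m$lr_pos, (m$se_pct / 100) / (1 - m$sp_pct / 100),
               tolerance = 1e-9)
  prev <- m$n_normalized / m$n_total
  expect_equal(m$posttest_prob_pos,
               posttest_probability(m$lr_pos, prev), tolerance = 1e-12)
  expect_true(m$auc >= 0.5 && m$auc <= 1)
  expect_true(m$auc_ci_low <= m$auc && m$auc <= m$auc_ci_high)
})
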