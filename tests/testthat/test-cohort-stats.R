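test_that("speed matching keeps trials inside the closed patient band", {
  keep <- match_speed_trials(c(0.6, 0.8, 1.2), 0.777, 0.305)
  expect_equal(keep, c(TRUE, TRUE, FALSE))   # band [0.472, 1.082]
  expect_true(all(match_speed_trials(c(0.1, 5), 1, 1e9)))
  expect_false(any(match_speed_trials(c(2, 3), 0.8, 0.1)))
  # closed interval: the endpoints are retained
  expect_true(all(match_speed_trials(c(0.777 - 0.305, 0.777 + 0.305),
                                     0.777, 0.305)))
  expect_error(match_speed_trials(1, 0.8, 0), "positive")
  # shift invariance: shifting all speeds and the band leaves the set alone
  set.seed(3)
  sp <- runif(20, 0.4, 1.2)
  expect_equal(match_speed_trials(sp, 0.8, 0.2),
               match_speed_trials(sp + 5, 5.8, 0.2))
})

test_that("the percent-change delta follows its identity", {
  expect_equal(delta_pct(0.777, 0.864), 11.197, tolerance = 1e-4)
  expect_equal(delta_pct(3.3, 3.3), 0)
  expect_equal(delta_pct(10, 5), -50)
  expect_error(delta_pct(0, 1), "non-zero")
  set.seed(4)
  for (i in 1:20) {
    a <- runif(1, -5, 5); p <- runif(1, -80, 80)
    if (a == 0) next
    expect_equal(delta_pct(a, a * (1 + p / 100)), p, tolerance = 1e-9)
  }
})

test_that("moment-based pooled t matches the closed form and raw samples", {
  # closed form against a sample exactly realizing the moments
  realize <- function(n, m, s) {
    z <- scale(rnorm(n))           # mean 0, sd 1 exactly
    as.numeric(m + s * z)
  }
  set.seed(5)
  x <- realize(36, 102.307, 16.146); y <- realize(22, 88.280, 12.406)
  ct <- pooled_t_from_moments(102.307, 16.146, 36, 88.280, 12.406, 22)
  expect_equal(unname(t.test(x, y, var.equal = TRUE)$statistic), ct$t,
               tolerance = 1e-10)
  cr <- compare_groups(x, y)
  expect_equal(cr$test, "pooled-t")
  expect_equal(cr$statistic, ct$t, tolerance = 1e-10)
})

test_that("the normality gate routes to rank tests for skewed samples", {
  set.seed(6)
  x <- rexp(30)^2; y <- rexp(30)^2 + 1
  cr <- compare_groups(x, y)
  expect_equal(cr$test, "Mann-Whitney")
  crp <- compare_groups(x, x - rexp(30)^2, paired = TRUE)
  expect_equal(crp$test, "Wilcoxon")
  z <- rnorm(20)
  expect_equal(compare_groups(z, z + rnorm(20, 1), paired = TRUE)$test,
               "paired-t")
  expect_error(compare_groups(rep(1, 5), rep(1, 5)), "zero variance")
  expect_error(compare_groups(1:2, 1:5), "at least 3")
})

test_that("Cohen's d follows its definitions", {
  set.seed(7)
  x <- rnorm(30)
  expect_equal(cohen_d(x, x + 0), 0)
  # a shift of one pooled SD gives d = 1
  y <- as.numeric(scale(rnorm(30)))
  expect_equal(cohen_d(y + 1, y), 1, tolerance = 1e-10)
  # moment realization of the cadence rows: d = 14.027 / pooled SD
  realize <- function(n, m, s) as.numeric(m + s * scale(rnorm(n)))
  a <- realize(36, 102.307, 16.146); b <- realize(22, 88.280, 12.406)
  sp <- pooled_t_from_moments(102.307, 16.146, 36, 88.280, 12.406, 22)$pooled_sd
  expect_equal(cohen_d(a, b), (102.307 - 88.280) / sp, tolerance = 1e-10)
  # paired: mean difference over SD of differences, absolute
  d <- rnorm(25, 0.4, 1)
  base <- rnorm(25)
  expect_equal(cohen_d(base + d, base, paired = TRUE),
               abs(mean(d)) / sd(d), tolerance = 1e-10)
})

test_that("improvement classification uses the strict distance rule", {
  expect_true(classify_improvement(0.41, 0.45, 0.52))
  # overshoot to the exact mirror distance is not improvement
  expect_false(classify_improvement(0.41, 0.63, 0.52))
  # baseline already at the control mean cannot improve
  expect_false(classify_improvement(0.52, 0.50, 0.52))
  # direction-agnostic: works when lower is better too
  expect_true(classify_improvement(20, 8, 5.5))
})

test_that("the improvement chi-square tests an even split", {
  r <- improvement_chi_square(23, 36)
  expect_equal(r$statistic, 2 * 25 / 18, tolerance = 1e-10)
  expect_equal(improvement_chi_square(18, 36)$statistic, 0)
  expect_equal(improvement_chi_square(36, 36)$statistic, 36)
  expect_error(improvement_chi_square(40, 36), "invalid")
})

test_that("bivariate correlation gates method and matches the exact rank p", {
  expect_equal(bivariate_correlation(1:10 + rnorm(10, 0, 1e-8), 1:10)$estimate,
               1, tolerance = 1e-6)
  expect_equal(bivariate_correlation(1:10 + rnorm(10, 0, 1e-8), -(1:10))$estimate,
               -1, tolerance = 1e-6)
  # clearly non-normal marginals force Spearman; its p is the exact
  # permutation probability, cross-checked by brute force over all 7! ranks
  x <- c(1, 1.1, 1.05, 0.9, 1.2, 8, 10)
  y <- c(0.2, 4, 1.2, 0.9, 2, 30, 28)
  r <- bivariate_correlation(x, y)
  expect_equal(r$method, "spearman")
  rho_obs <- cor(rank(x), rank(y))
  n <- length(x)
  idx <- seq_len(n)
  # enumerate permutations via recursive generation
  permute <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in permute(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    out
  }
  rhos <- vapply(permute(idx), function(p) cor(rank(x), rank(y)[p]),
                 numeric(1))
  p_exact <- mean(abs(rhos) >= abs(rho_obs) - 1e-12)
  expect_equal(r$p_value, p_exact, tolerance = 1e-8)
})

test_that("paired power analysis matches the noncentral-t search", {
  expect_equal(paired_power_sample_size(0.5, 0.80, 0.05, TRUE), 34)
  expect_equal(paired_power_sample_size(1.0, 0.80, 0.05, TRUE), 10)
  expect_gt(paired_power_sample_size(0.5, 0.9999), 34)
  expect_error(paired_power_sample_size(0), "non-zero")
  expect_error(paired_power_sample_size(0.5, 1.2), "power")
  # cross-check against the closed-form power solver
  pw <- stats::power.t.test(delta = 0.5, sd = 1, power = 0.80, type = "paired")
  expect_equal(paired_power_sample_size(0.5), ceiling(pw$n))
})
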