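test_that("welch_t matches the closed form and t.test", {
  s <- welch_t(group_summary(63, 0.84, 0.42), group_summary(50, 0.67, 0.34))
  # hand evaluation of the Welch formulas on the printed summaries
  expect_equal(s$t, 2.378, tolerance = 1e-3)
  expect_equal(s$df, 110.95, tolerance = 1e-4)

  same <- group_summary(20, 1.5, 0.3)
  id <- welch_t(same, same)
  expect_equal(id$t, 0)
  expect_equal(id$p, 1)

  # raw-vector route equals the summary route exactly, and equals t.test
  set.seed(12)
  a <- rnorm(14, 1, 0.5); b <- rnorm(19, 0.7, 0.8)
  w1 <- welch_t(a, b)
  w2 <- welch_t(group_summary(length(a), mean(a), sd(a)),
                group_summary(length(b), mean(b), sd(b)))
  expect_identical(w1, w2)
  ref <- t.test(a, b)
  expect_equal(w1$t, unname(ref$statistic))
  expect_equal(w1$df, unname(ref$parameter))
  expect_equal(w1$p, ref$p.value)

  # antisymmetry
  w3 <- welch_t(b, a)
  expect_equal(w3$t, -w1$t)
  expect_equal(w3$df, w1$df)
  expect_equal(w3$p, w1$p)

  expect_error(welch_t(group_summary(5, 1, 0), group_summary(5, 2, 0)),
               "zero")
})

test_that("hedges_g reproduces the published worked examples", {
  expect_equal(round(hedges_g(group_summary(63, 0.84, 0.42),
                              group_summary(50, 0.67, 0.34)), 2), 0.44)
  expect_equal(round(hedges_g(group_summary(63, 0.99, 0.59),
                              group_summary(50, 0.76, 0.36)), 2), 0.46)
  expect_equal(round(hedges_g(group_summary(31, 2.66, 0.61),
                              group_summary(25, 2.22, 0.55)), 2), 0.74)
  expect_equal(hedges_g(group_summary(10, 1, 0.5),
                        group_summary(12, 1, 0.7)), 0)
  # sign follows the mean difference, like t
  set.seed(2)
  a <- rnorm(10, 2); b <- rnorm(10, 1)
  expect_equal(sign(hedges_g(a, b)), sign(welch_t(a, b)$t))
})

test_that("bonferroni is the capped product, monotone and idempotent", {
  expect_equal(bonferroni(0.004, 5), 0.02)
  expect_equal(bonferroni(0.3, 5), 1)
  expect_equal(bonferroni(0.123, 1), 0.123)
  p <- seq(0.01, 0.9, by = 0.07)
  expect_true(all(diff(bonferroni(p, 4)) >= 0))          # monotone in p
  expect_true(all(bonferroni(0.04, 1:30) ==
                  cummax(bonferroni(0.04, 1:30))))        # monotone in m
  expect_equal(bonferroni(bonferroni(0.3, 5), 1), 1)      # cap idempotent
  expect_error(bonferroni(0, 5), "p must")
})

test_that("pearson_r matches the covariance / sd-product oracle", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_r(c(1, 2, 3), c(1, -2, 1))$r, 0)
  set.seed(33)
  x <- rnorm(20); y <- 0.4 * x + rnorm(20)
  res <- pearson_r(x, y)
  r_ref <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$r, r_ref)
  t_ref <- r_ref * sqrt(18 / (1 - r_ref^2))
  expect_equal(res$p, 2 * pt(-abs(t_ref), 18))
  # incomplete pairs are dropped
  y[3] <- NA
  expect_equal(pearson_r(x, y)$n, 19)
  expect_error(pearson_r(1:5, rep(2, 5)), "variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("linear_main_effects equals the normal-equations oracle", {
  set.seed(44)
  d <- data.frame(group = rep(c("HC", "SZ"), each = 12),
                  sex = sample(c("M", "F"), 24, replace = TRUE),
                  cpz = rlnorm(24, 5, 0.4))
  y <- 1 + 0.5 * (d$group == "SZ") + 0.001 * d$cpz + rnorm(24, sd = 0.3)
  res <- linear_main_effects(y, d)
  ref <- oracle_main_effects(y, d)
  expect_equal(res$term, ref$term)
  expect_equal(res$F, ref$F)
  expect_equal(res$p, ref$p)

  # location invariance of F
  res2 <- linear_main_effects(y + 100, d)
  expect_equal(res2$F, res$F)

  # y identical across sex within every group: sex adds zero sum of
  # squares, so its Type II F is 0
  d0 <- expand.grid(rep = 1:3, sex = c("M", "F"), group = c("HC", "SZ"),
                    stringsAsFactors = FALSE)
  y0 <- d0$rep + 5 * (d0$group == "SZ")
  res3 <- linear_main_effects(y0, d0[, c("group", "sex")])
  expect_lt(abs(res3$F[res3$term == "sex"]), 1e-10)

  dd <- data.frame(a = rnorm(10))
  dd$b <- 2 * dd$a
  expect_error(linear_main_effects(rnorm(10), dd), "collinear")
  expect_error(linear_main_effects(rnorm(3),
                                   data.frame(g = c("a", "b", "a"),
                                              x = rnorm(3))),
               "more observations")
})

test_that("chi2_2x2 reproduces the published balance statistics", {
  cobre <- matrix(c(58, 14, 51, 23), 2, byrow = TRUE)   # SZ, HC x M, F
  res <- chi2_2x2(cobre)
  expect_equal(round(res$chi2, 3), 2.033)
  # p consistent with the statistic under chi-squared(1)
  expect_equal(res$p, pchisq(res$chi2, 1, lower.tail = FALSE))
  ucla <- matrix(c(38, 12, 44, 19), 2, byrow = TRUE)
  expect_equal(round(chi2_2x2(ucla)$chi2, 3), 0.267)

  # a proportional table is exactly independent
  expect_equal(chi2_2x2(matrix(c(20, 40, 10, 20), 2))$chi2, 0)

  # oracle: stats::chisq.test, with and without correction
  set.seed(6)
  for (i in 1:10) {
    tab <- matrix(rpois(4, 20) + 1, 2)
    for (cc in c(TRUE, FALSE)) {
      ref <- chisq.test(tab, correct = cc)
      got <- chi2_2x2(tab, continuity = cc)
      expect_equal(got$chi2, unname(ref$statistic))
      expect_equal(got$p, ref$p.value)
    }
    # the uncorrected statistic dominates the corrected one
    expect_gte(chi2_2x2(tab, FALSE)$chi2, chi2_2x2(tab, TRUE)$chi2)
  }
  expect_error(chi2_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "marginal")
})

test_that("compare_groups assembles the ROI contrast row", {
  a <- group_summary(31, 2.66, 0.61); b <- group_summary(25, 2.22, 0.55)
  row <- compare_groups(a, b, m = 5)
  expect_equal(row$p_bonf, min(1, 5 * row$p))
  expect_equal(round(row$g, 2), 0.74)
  expect_equal(sign(row$g), sign(row$t))
})
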