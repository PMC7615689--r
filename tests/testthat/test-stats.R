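test_that("change scores are the defining differences", {
  cs <- change_scores(rep(1.2, 40), rep(0.8, 5), rep(0.8, 5))
  expect_equal(cs$training_change, 0)
  expect_equal(cs$transfer_change, 0)
  cs2 <- change_scores(c(rep(1, 10), rep(1.25, 20), rep(1.5, 10)),
                       pre = rep(0.6, 5), post = rep(0.9, 5))
  expect_equal(cs2$early, 1)
  expect_equal(cs2$late, 1.5)
  expect_equal(cs2$training_change, 0.5)
  expect_equal(cs2$transfer_change, 0.3, tolerance = 1e-12)
  # linear ramp scaled to [0, 1] over 100 trials
  ramp <- (0:99) / 99
  cs3 <- change_scores(ramp, 0.5, 0.5)
  expect_equal(cs3$training_change, 90 / 99, tolerance = 1e-12)
  expect_error(change_scores(rep(1, 15), 1, 1), "insufficient")
})

test_that("two-sample and paired t-tests report classical t and Cohen's d", {
  r <- two_sample_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(round(r$t, 3), -3.674)
  expect_equal(r$d, -3)
  expect_equal(r$df, 4)
  x <- c(2, 4, 6, 8); y <- c(1, 2, 5, 6)
  p <- paired_t(x, y)
  expect_equal(p$d, mean(x - y) / sd(x - y))
  expect_equal(p$t, unname(t.test(x, y, paired = TRUE)$statistic))
})

test_that("one-way ANOVA agrees with a brute-force projection oracle", {
  set.seed(33)
  g <- factor(rep(letters[1:3], each = 8))
  y <- rnorm(24, mean = as.integer(g) * 0.5)
  rep_ <- one_way_anova(y, g)
  # oracle: explicit sums of squares from group means
  gm <- tapply(y, g, mean)
  ss_eff <- sum(table(g) * (gm - mean(y))^2)
  ss_err <- sum((y - gm[g])^2)
  F_oracle <- (ss_eff / 2) / (ss_err / 21)
  expect_equal(rep_$F, F_oracle, tolerance = 1e-8)
  expect_equal(rep_$eta2p, ss_eff / (ss_eff + ss_err), tolerance = 1e-8)
  expect_equal(rep_$df1, 2)
  expect_equal(rep_$df2, 21)
  # identical groups: F = 0, eta2p = 0
  r0 <- one_way_anova(rep(c(1, 2, 3), 2), rep(c("a", "b"), each = 3))
  expect_equal(r0$F, 0)
  expect_equal(r0$eta2p, 0)
  expect_error(one_way_anova(1:4, rep("a", 4)), "degenerate")
})

test_that("follow-up t-tests use the pooled error and Bonferroni", {
  set.seed(34)
  y <- rnorm(30, rep(c(0, 1, 3), each = 10))
  g <- rep(c("a", "b", "c"), each = 10)
  rep_ <- one_way_anova(y, g)
  fu <- rep_$followups
  expect_equal(nrow(fu), 3L)
  expect_true(all(fu$p_bonf >= fu$p))
  expect_true(all(fu$p_bonf <= 1))
  expect_equal(fu$p_bonf, pmin(1, fu$p * 3))
  expect_true(all(fu$df == 27))
  # explicit family size
  rep5 <- one_way_anova(y, g, family_size = 5)
  expect_equal(rep5$followups$p_bonf, pmin(1, fu$p * 5))
})

test_that("ANCOVA matches nested-model Type-II sums of squares", {
  set.seed(35)
  d <- data.frame(g = rep(c("a", "b", "c"), each = 9))
  d$cov <- rnorm(27)
  d$y <- 0.8 * d$cov + (d$g == "b") * 0.5 + rnorm(27, sd = 0.7)
  tab <- ancova(d, dv = "y", factors = "g", covariates = "cov")
  # oracle: residual-SS differences between nested least-squares fits
  full <- lm(y ~ cov + g, d)
  no_g <- lm(y ~ cov, d)
  no_cov <- lm(y ~ g, d)
  ss_err <- sum(residuals(full)^2)
  ss_g <- sum(residuals(no_g)^2) - ss_err
  ss_cov <- sum(residuals(no_cov)^2) - ss_err
  df2 <- 27 - 4
  expect_equal(tab$F[tab$term == "g"], (ss_g / 2) / (ss_err / df2),
               tolerance = 1e-8)
  expect_equal(tab$F[tab$term == "cov"], ss_cov / (ss_err / df2),
               tolerance = 1e-8)
  expect_equal(tab$eta2p[tab$term == "g"], ss_g / (ss_g + ss_err),
               tolerance = 1e-8)
  expect_error(ancova(within(d, dup <- cov), "y", "g", c("cov", "dup")),
               "degenerate|aliased")
})

test_that("effect-size conversions are exact and invertible", {
  expect_equal(round(eta2_to_f(0.054), 2), 0.24)
  expect_equal(eta2_to_f(0.054), sqrt(0.054 / 0.946))
  expect_equal(eta2_to_f(0), 0)
  expect_equal(eta2_to_f(0.5), 1)
  for (e in c(0.01, 0.054, 0.2, 0.8)) {
    expect_equal(f_to_eta2(eta2_to_f(e)), e, tolerance = 1e-12)
  }
  expect_error(eta2_to_f(1), "\\[0, 1\\)")
  expect_error(f_to_eta2(-0.1), ">= 0")
})

test_that("noncentral-F power is monotone and the planning search is sound", {
  f <- eta2_to_f(0.054)
  p1 <- rm_anova_power(300, f, 15, 2, 0.663)
  p2 <- rm_anova_power(450, f, 15, 2, 0.663)
  expect_gt(p2, p1)
  N95 <- required_sample_size(f, 0.05, 0.95, 15, 2, 0.663)
  N80 <- required_sample_size(f, 0.05, 0.80, 15, 2, 0.663)
  expect_lt(N80, N95)
  Nbig <- required_sample_size(2 * f, 0.05, 0.95, 15, 2, 0.663)
  expect_lt(Nbig, N95)
  expect_equal(N95 %% 15, 0)
  # the returned N is minimal among multiples of the group count
  expect_gte(rm_anova_power(N95, f, 15, 2, 0.663), 0.95)
  expect_lt(rm_anova_power(N95 - 15, f, 15, 2, 0.663), 0.95)
})

test_that("correlation utilities behave at the boundaries", {
  x <- rnorm(20)
  r <- pearson_r(x, x)
  expect_equal(r$r, 1)
  expect_error(pearson_r(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "3 pairs")
  cohort <- data.frame(training_change = x, transfer_change = 2 * x)
  expect_equal(training_transfer_correlation(cohort)$r, 1)
})

test_that("bonferroni adjustment respects its bounds", {
  p <- c(0.001, 0.04, 0.5)
  expect_equal(bonferroni(p), pmin(1, p * 3))
  expect_equal(bonferroni(p, family_size = 10), pmin(1, p * 10))
  expect_true(all(bonferroni(p) >= p))
})
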