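# The testing ladder: Levene gate, ANOVA, Tukey, Dunnett T3, Student t,
# compact letters.

test_that("levene equals the ANOVA on absolute deviations and matches car", {
  skip_if_not_installed("car")
  withr::with_seed(11, {
    for (rep in 1:5) {
      d <- groups_df(list(a = rnorm(10), b = rnorm(10, 0, 3), c = rnorm(10, 1)))
      lev <- levene_test(d, value, group)
      # independent oracle: car's mean-centred Levene
      oracle <- car::leveneTest(value ~ factor(group), data = d, center = mean)
      expect_equal(lev$statistic, oracle$`F value`[1], tolerance = 1e-10)
      expect_equal(lev$p_value, oracle$`Pr(>F)`[1], tolerance = 1e-10)
    }
  })
})

test_that("levene handles equal-deviation and degenerate inputs", {
  d <- groups_df(list(a = c(1, 3), b = c(2, 4)))
  lev <- levene_test(d, value, group)
  expect_equal(lev$statistic, 0)
  expect_equal(lev$p_value, 1)
  dg <- groups_df(list(a = c(5, 5), b = c(5, 5)))
  levg <- levene_test(dg, value, group)
  expect_equal(levg$p_value, 1)
  expect_true(levg$degenerate)
  expect_error(levene_test(groups_df(list(a = 1, b = c(1, 2))), value, group),
               "fewer than 2")
})

test_that("one-way ANOVA matches the sum-of-squares oracle and t^2 identity", {
  withr::with_seed(12, {
    g <- list(a = rnorm(8, 1), b = rnorm(12, 1.5), c = rnorm(10, 0.5))
    d <- groups_df(g)
    res <- oneway_anova(d, value, group)
    # brute-force sums of squares
    all_v <- unlist(g); k <- 3; N <- length(all_v)
    ssb <- sum(sapply(g, function(x) length(x) * (mean(x) - mean(all_v))^2))
    ssw <- sum(sapply(g, function(x) sum((x - mean(x))^2)))
    f_or <- (ssb / (k - 1)) / (ssw / (N - k))
    expect_equal(res$statistic, f_or, tolerance = 1e-10)
    expect_equal(res$p_value, pf(f_or, k - 1, N - k, lower.tail = FALSE),
                 tolerance = 1e-12)
    # two groups: F = t^2 of the pooled t-test
    d2 <- groups_df(g[1:2])
    res2 <- oneway_anova(d2, value, group)
    tt <- student_t(g$a, g$b)
    expect_equal(res2$statistic, tt$statistic^2, tolerance = 1e-10)
    expect_equal(res2$p_value, tt$p_value, tolerance = 1e-10)
  })
  # identical group means
  same <- groups_df(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(oneway_anova(same, value, group)$statistic, 0)
  expect_equal(oneway_anova(same, value, group)$p_value, 1)
})

test_that("student_t matches the textbook pooled formula and is symmetric", {
  withr::with_seed(13, {
    a <- rnorm(7, 1); b <- rnorm(9, 0.4)
  })
  res <- student_t(a, b)
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  t_or <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  expect_equal(res$statistic, t_or, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(abs(t_or), 14, lower.tail = FALSE),
               tolerance = 1e-12)
  swapped <- student_t(b, a)
  expect_equal(swapped$statistic, -res$statistic)
  expect_equal(swapped$p_value, res$p_value)
  expect_equal(student_t(a, a)$statistic, 0)
  expect_equal(student_t(a, a)$p_value, 1)
})

test_that("tukey_hsd agrees with TukeyHSD and reduces to the pooled t at k = 2", {
  withr::with_seed(14, {
    g <- list(a = rnorm(9, 0), b = rnorm(9, 0.8), c = rnorm(9, 1.6))
  })
  d <- groups_df(g)
  res <- tukey_hsd(d, value, group)
  # independent route: stats::TukeyHSD on an aov fit
  fit <- TukeyHSD(aov(value ~ group, data = d))$group
  expect_equal(sort(res$p_adj), sort(unname(fit[, "p adj"])), tolerance = 1e-8)
  # k = 2 reduces to the pooled t-test (q = t * sqrt(2))
  d2 <- groups_df(g[1:2])
  r2 <- tukey_hsd(d2, value, group)
  tt <- student_t(g$a, g$b)
  expect_equal(r2$statistic, abs(tt$statistic) * sqrt(2), tolerance = 1e-12)
  expect_equal(r2$p_adj, tt$p_value, tolerance = 1e-10)
  # two equal groups
  same <- groups_df(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(tukey_hsd(same, value, group)$p_adj, 1, tolerance = 1e-12)
})

test_that("dunnett_t3 reduces to the Welch t at k = 2 and handles degeneracy", {
  withr::with_seed(15, {
    a <- rnorm(8, 0, 1); b <- rnorm(14, 1, 4)
  })
  r <- dunnett_t3(groups_df(list(a = a, b = b)), value, group)
  wt <- t.test(a, b)  # Welch
  expect_equal(abs(r$statistic), abs(unname(wt$statistic)), tolerance = 1e-12)
  expect_equal(r$df, unname(wt$parameter), tolerance = 1e-10)
  # m = 1: SMM is the |t| distribution, so p matches the two-sided Welch p
  expect_equal(r$p_adj, wt$p.value, tolerance = 1e-8)
  # identical groups -> p = 1; zero-variance unequal means -> p = 0
  same <- groups_df(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(dunnett_t3(same, value, group)$p_adj, 1)
  apart <- groups_df(list(a = c(2, 2), b = c(3, 3)))
  expect_equal(dunnett_t3(apart, value, group)$p_adj, 0)
})

test_that("the SMM distribution function is coherent", {
  # monotone in q, increasing in m makes the tail heavier, df -> Inf limit
  qs <- c(1, 2, 3)
  expect_true(all(diff(psmm(qs, 3, 10)) > 0))
  expect_gt(psmm(2.5, 1, 10), psmm(2.5, 6, 10))
  expect_equal(psmm(2, 3, Inf), (2 * pnorm(2) - 1)^3, tolerance = 1e-10)
  # quantile inverts the distribution
  q95 <- mucotrace:::qsmm(0.95, 3, 12)
  expect_equal(mucotrace:::psmm(q95, 3, 12), 0.95, tolerance = 1e-7)
})

test_that("compare_groups routes on the Levene gate and annotates letters", {
  withr::with_seed(16, {
    homo <- list(a = rnorm(12, 0), b = rnorm(12, 5), c = rnorm(12, 10))
    hetero <- list(a = rnorm(12, 0, 0.1), b = rnorm(12, 5, 10), c = rnorm(12, 10, 0.1))
  })
  ch <- compare_groups(groups_df(homo), value, group)
  expect_equal(ch$method, "Tukey HSD")
  expect_equal(ch$letters$letters, c("a", "b", "c"))
  cht <- compare_groups(groups_df(hetero), value, group)
  expect_equal(cht$method, "Dunnett T3")
  # tidiers
  td <- tidy(ch)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  gl <- glance(ch)
  expect_equal(gl$method, "Tukey HSD")
  expect_true(gl$anova_p < 0.05)
  # no separation: a single shared letter
  withr::with_seed(17, null <- list(a = rnorm(10), b = rnorm(10), c = rnorm(10)))
  cn <- compare_groups(groups_df(null), value, group)
  expect_equal(cn$letters$letters, c("a", "a", "a"))
})

test_that("Tukey and T3 concur on balanced homoscedastic groups with n >= 10", {
  # T3 refers each pair to the studentized maximum modulus, which ignores the
  # positive correlation among pairwise contrasts, so its adjusted p can sit
  # well above Tukey's away from the tails; what must hold is that the two
  # procedures make the same significance calls and stay close where it
  # matters, near the decision threshold.
  withr::with_seed(18, {
    for (rep in 1:3) {
      g <- list(a = rnorm(12, 0), b = rnorm(12, 0.6), c = rnorm(12, 1.1))
      d <- groups_df(g)
      tk <- tukey_hsd(d, value, group)
      t3 <- dunnett_t3(d, value, group)
      expect_equal(t3$significant, tk$significant)
      tail_pairs <- tk$p_adj < 0.1
      if (any(tail_pairs)) {
        expect_lt(max(abs(tk$p_adj[tail_pairs] - t3$p_adj[tail_pairs])), 0.05)
      }
    }
  })
})

test_that("dunnett_t3 keeps familywise error at or below nominal under heteroscedastic nulls", {
  n_sim <- 1000
  withr::with_seed(19, {
    hits <- vapply(seq_len(n_sim), function(i) {
      d <- groups_df(list(a = rnorm(8, 0, 0.2), b = rnorm(12, 0, 3), c = rnorm(6, 0, 1)))
      any(dunnett_t3(d, value, group)$significant)
    }, TRUE)
  })
  mc_se <- sqrt(0.05 * 0.95 / n_sim)
  expect_lte(mean(hits), 0.05 + 2 * mc_se)
})
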