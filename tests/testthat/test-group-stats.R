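test_that("the omnibus normality statistic matches its reference values", {
  # frozen oracle values computed from the standard K^2 formulas
  x1 <- round(sin(1:30) * 7 + (1:30) * 0.5, 6)
  r1 <- dagostino_pearson(x1)
  expect_equal(r1$statistic, 0.3726713563, tolerance = 1e-9)
  expect_equal(r1$p_value, 0.82999493704, tolerance = 1e-9)
  x2 <- round(exp(seq(0, 2.5, length.out = 20)), 6)
  r2 <- dagostino_pearson(x2)
  expect_equal(r2$statistic, 3.3115648727, tolerance = 1e-9)
  expect_equal(r2$p_value, 0.19094259682, tolerance = 1e-9)
  # symmetric sample: skewness z is exactly zero, kurtosis z carries K^2
  x3 <- round(seq(-2, 2, length.out = 50), 6)
  r3 <- dagostino_pearson(x3)
  expect_equal(r3$z_skewness, 0)
  expect_equal(r3$z_kurtosis, -3.4367735001, tolerance = 1e-8)
  expect_equal(r3$statistic, r3$z_kurtosis^2, tolerance = 1e-9)
})

test_that("degenerate and small samples are flagged not applicable", {
  expect_false(dagostino_pearson(rep(5, 100))$applicable)
  expect_false(dagostino_pearson(1:7)$applicable)
  expect_true(is.na(dagostino_pearson(1:7)$p_value))
})

test_that("the normality screen is calibrated and powered", {
  set.seed(2024)
  reps <- 200
  p_norm <- replicate(reps, dagostino_pearson(rnorm(500))$p_value)
  p_heavy <- replicate(reps, dagostino_pearson(rt(500, df = 3))$p_value)
  expect_gt(mean(p_heavy < 0.05), 0.95)
  expect_gt(mean(p_norm < 0.05), 0.015)
  expect_lt(mean(p_norm < 0.05), 0.10)
})

test_that("Kruskal-Wallis H matches direct evaluation of the rank formula", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)))
  # H = 12/(N(N+1)) * sum n_i Rbar_i^2 - 3(N+1) = 7.2 for these ranks
  expect_equal(kw$H, 7.2, tolerance = 1e-9)
  expect_equal(kw$p_value, pchisq(7.2, 2, lower.tail = FALSE), tolerance = 1e-9)
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))$H, 0)
  expect_equal(kruskal_wallis(list(c(5, 5), c(5, 5)))$p_value, 1)
  expect_error(kruskal_wallis(list(1:3)), "groups")
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(10)
  g <- list(rlnorm(20), rlnorm(25, 0.4), rlnorm(15, -0.2))
  h1 <- kruskal_wallis(g)$H
  h2 <- kruskal_wallis(lapply(g, function(x) exp(x)))$H
  h3 <- kruskal_wallis(lapply(g, function(x) -1 / x))$H
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_equal(h1, h3, tolerance = 1e-12)
})

test_that("Dunn z and adjusted p match hand evaluation on pooled ranks", {
  dn <- dunn_vs_control(list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9)), 1L)
  # mean ranks 2, 5, 8; SE = sqrt((N(N+1)/12) * (2/3)) = sqrt(5)
  expect_equal(dn$z, c(3, 6) / sqrt(5), tolerance = 1e-9)
  expect_equal(dn$p_value, 2 * pnorm(-abs(dn$z)), tolerance = 1e-12)
  expect_equal(dn$p_adjusted, pmin(1, dn$p_value * 2))
  expect_equal(dn$sign, c(1, 1))
  # identical groups give z = 0, capped adjusted p = 1
  dn0 <- dunn_vs_control(list(1:9, 1:9), 1L)
  expect_equal(dn0$z, 0)
  expect_equal(dn0$p_adjusted, 1)
  expect_error(dunn_vs_control(list(numeric(0), 1:3), 1L), "control")
})

test_that("change calls follow the gated significance-and-direction rule", {
  set.seed(77)
  n <- 60
  df <- data.frame(
    region = "R",
    group = rep(c("control", "up_g", "null_g"), each = n),
    v = c(rnorm(n, 10), rnorm(n, 14), rnorm(n, 10)))
  cmp <- compare_endpoint(df, "v", "control")
  cc <- cmp$comparisons
  expect_equal(cc$call[cc$group == "up_g"], "up")
  expect_equal(cc$call[cc$group == "null_g"], "no_change")
  # non-significant omnibus forces every call to no_change
  df2 <- df; df2$v <- rnorm(3 * n, 10)
  cmp2 <- compare_endpoint(df2, "v", "control")
  if (cmp2$kw_p >= 0.05) expect_true(all(cmp2$comparisons$call == "no_change"))
  # strong downward shift
  df3 <- df; df3$v[df3$group == "up_g"] <- rnorm(n, 6)
  cmp3 <- compare_endpoint(df3, "v", "control")
  expect_equal(cmp3$comparisons$call[cmp3$comparisons$group == "up_g"], "down")
})
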