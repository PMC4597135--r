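test_that("t-tests: one-sample, pooled two-sample, paired", {
  # one-sample {1,2,3} vs 0: t = 2 / (1/sqrt(3)) = 3.4641, df 2
  one <- t_test_stat(c(1, 2, 3), mu = 0)
  expect_equal(one$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-10)
  expect_equal(one$df, 2)
  expect_equal(one$p_value,
               stats::t.test(c(1, 2, 3), mu = 0)$p.value, tolerance = 1e-10)

  # identical groups: t = 0, p = 1
  x <- c(1, 2, 3, 4)
  same <- t_test_stat(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  # pooled df = n1 + n2 - 2 and agreement with var.equal t.test
  set.seed(2)
  a <- rnorm(20); b <- rnorm(20, 5)
  two <- t_test_stat(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(two$df, 38)
  expect_equal(two$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(two$p_value, ref$p.value, tolerance = 1e-10)
  expect_lt(two$p_value, 1e-6)
  # Cohen's d: mean difference over pooled SD
  sp <- sqrt((19 * var(a) + 19 * var(b)) / 38)
  expect_equal(two$effect_size, (mean(a) - mean(b)) / sp)

  # paired reduces to one-sample on differences
  pr <- t_test_stat(a, a + 1, paired = TRUE)
  expect_equal(pr$statistic, t_test_stat(a - (a + 1), mu = 0)$statistic)

  expect_error(t_test_stat(rep(1, 5), mu = 1), "zero variance")
  expect_error(t_test_stat(rep(1, 5), rep(1, 6), paired = TRUE), "equal length")
})

test_that("exact sign test reproduces hand-enumerated tails", {
  # 29/40: two-tailed p = 0.006 at 3 d.p.
  s <- sign_test_exact(29, 40)
  expect_equal(round(s$p_value, 3), 0.006)
  expect_equal(s$p_value, 2 * sum(dbinom(29:40, 40, 0.5)), tolerance = 1e-12)

  # dead centre: p capped at 1
  expect_equal(sign_test_exact(20, 40)$p_value, 1)

  # 17/20 = 2 * 1351 / 2^20
  expect_equal(sign_test_exact(17, 20)$p_value, 2 * 1351 / 2^20,
               tolerance = 1e-12)

  # symmetry k <-> n - k
  for (k in c(0, 3, 11, 20)) {
    expect_equal(sign_test_exact(k, 40)$p_value,
                 sign_test_exact(40 - k, 40)$p_value)
  }
  expect_error(sign_test_exact(5, 4), "k <= n")
})

test_that("Spearman: mid-ranks, monotone invariance, t approximation", {
  expect_equal(spearman_test(1:10, (1:10)^3)$statistic, 1)
  expect_equal(spearman_test(1:10, -(1:10))$statistic, -1)
  expect_equal(spearman_test(1:10, (1:10)^3)$p_value, 0)

  # x = 1..5, y = (1,3,2,5,4): sum d^2 = 4 => rho = 1 - 24/120 = 0.8
  s <- spearman_test(1:5, c(1, 3, 2, 5, 4))
  expect_equal(s$statistic, 0.8)
  expect_equal(s$statistic,
               cor(1:5, c(1, 3, 2, 5, 4), method = "spearman"))

  # invariance under strictly monotone transforms of either argument
  set.seed(3)
  x <- rnorm(25); y <- rnorm(25)
  base <- spearman_test(x, y)$statistic
  expect_equal(spearman_test(exp(x), y)$statistic, base)
  expect_equal(spearman_test(x, y^3 + 5 * y)$statistic, base)

  # t approximation: agree with cor.test's asymptotic p on tie-free data
  ref <- stats::cor.test(x, y, method = "spearman")
  got <- spearman_test(x, y)
  expect_equal(got$statistic, unname(ref$estimate), tolerance = 1e-10)

  expect_error(spearman_test(rep(1, 10), rnorm(10)), "constant")
  expect_error(spearman_test(1:3, 3:1), "n >= 4")
})

test_that("partial Spearman residualizes ranks and matches its oracle", {
  set.seed(4)
  # covariate independent of a perfectly monotone pair: rho ~ 1
  x <- 1:30
  y <- x^2
  z <- rnorm(30)
  expect_gt(partial_spearman(x, y, z)$statistic, 0.95)

  # y equal to the covariate: fully explained
  expect_error(partial_spearman(rnorm(30), z, z), "fully explained")

  # random instances match the brute-force rank-regression oracle
  for (i in 1:10) {
    x <- rnorm(30); y <- rnorm(30)
    z <- cbind(rnorm(30), rnorm(30))
    got <- partial_spearman(x, y, z)
    expect_equal(got$statistic, partial_spearman_oracle(x, y, z),
                 tolerance = 1e-10)
    expect_equal(got$df, 30 - 2 - 2)
  }

  expect_error(partial_spearman(rnorm(30), rnorm(30),
                                cbind(1:30, 2 * (1:30))), "collinear")
  expect_error(partial_spearman(rnorm(5), rnorm(5), cbind(rnorm(5), rnorm(5))),
               "covariates")
})

test_that("type-III ANCOVA: symmetry, SS decomposition, detection", {
  # values symmetric across groups at every covariate value => group F = 0
  # (the shared values must not be collinear with the covariate, or the
  # full model is saturated and F degenerates to 0/0)
  cov <- rep(1:10, 2)
  g <- rep(c("a", "b"), each = 10)
  half <- 2 * (1:10) + 3 + rep(c(0.5, -0.5), 5)
  res <- ancova_type3(rep(half, 2), g, cov)
  expect_lt(abs(res$group$statistic), 1e-8)
  expect_lt(abs(res$interaction$statistic), 1e-8)

  # SS decomposition on a balanced orthogonal design
  set.seed(5)
  vals2 <- rnorm(20)
  res2 <- ancova_type3(vals2, g, cov)
  cv <- cov - mean(cov)
  gg <- ifelse(g == "a", 1, -1)
  X <- cbind(1, gg, cv, gg * cv)
  fitf <- lm.fit(X, vals2)
  rss <- sum(fitf$residuals^2)
  ss_tot <- sum((vals2 - mean(vals2))^2)
  ss_effects <- sum(vapply(res2, function(r) {
    r$effect_size / (1 - r$effect_size) * rss
  }, numeric(1)))
  expect_equal(ss_tot, ss_effects + rss, tolerance = 1e-8)

  # group effect detected when values depend only on group
  set.seed(6)
  g3 <- rep(c("a", "b"), each = 30)
  v3 <- ifelse(g3 == "a", 1, 0) + rnorm(60, 0, 0.3)
  c3 <- rnorm(60)
  res3 <- ancova_type3(v3, g3, c3)
  expect_lt(res3$group$p_value, 1e-6)
  expect_gt(res3$interaction$p_value, 0.01)
  # partial eta squared within [0, 1]
  for (r in res3) {
    expect_gte(r$effect_size, 0); expect_lte(r$effect_size, 1)
  }

  # null calibration: permuted labels give roughly uniform group p
  set.seed(7)
  pvals <- replicate(200, {
    ancova_type3(rnorm(20), sample(g), rnorm(20))$group$p_value
  })
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)

  expect_error(ancova_type3(rnorm(10), rep("a", 10), rnorm(10)), "two groups")
  expect_error(ancova_type3(rnorm(6), rep(c("a", "b"), 3), rep(1, 6)),
               "rank-deficient")
})

test_that("Bonferroni correction is capped, monotone, and family-checked", {
  expect_equal(bonferroni(0.01, 3), 0.03)
  expect_equal(bonferroni(0.5, 3), 1)
  p <- c(0.001, 0.02, 0.3)
  expect_true(all(diff(bonferroni(p, 5)) >= 0))
  expect_error(bonferroni(c(0.1, 0.2), 1), "family size")
})

test_that("demographics summary reproduces the packaged patient table", {
  t1 <- load_table1()
  expect_equal(nrow(t1), 20)
  s <- table1_summary(t1)
  get <- function(col, field) s[s$column == col, field]
  expect_equal(get("lde", "mean_rounded"), 960)
  expect_equal(get("age", "mean_rounded"), 68)
  expect_equal(get("updrs_iii", "mean_rounded"), 20)
  expect_equal(get("ace_r", "mean_rounded"), 92)
  expect_equal(get("mmse", "mean_rounded"), 28)
  expect_equal(get("duration", "mean_rounded"), 12)
  expect_equal(get("stage", "mean_rounded"), 2)
  expect_equal(get("age", "min"), 48)
  expect_equal(get("age", "max"), 81)

  # single-row table: mean is the row, SD reported absent
  one <- table1_summary(t1[1, ])
  expect_equal(one$mean[one$column == "age"], 74)
  expect_true(all(is.na(one$sd)))

  expect_error(table1_summary(t1[, setdiff(names(t1), "lde")]), "lde")
})
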