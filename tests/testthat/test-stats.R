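test_that("summary-statistics ANOVA equals raw-data one-way ANOVA", {
  set.seed(21)
  for (i in 1:100) {
    k <- sample(2:4, 1)
    ns <- sample(3:12, k, replace = TRUE)
    y <- unlist(lapply(ns, function(n) rnorm(n, mean = runif(1, -2, 2))))
    g <- factor(rep(seq_len(k), ns))
    s <- tibble::tibble(
      n = ns,
      mean = as.numeric(tapply(y, g, mean)),
      sd = as.numeric(tapply(y, g, sd))
    )
    mine <- anova_from_summaries(s)
    ref <- oneway.test(y ~ g, var.equal = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-10)
  }
})

test_that("two-group summary ANOVA equals the squared pooled t statistic", {
  set.seed(5)
  a <- rnorm(12, 1); b <- rnorm(9, 0.2)
  s <- tibble::tibble(n = c(12, 9), mean = c(mean(a), mean(b)), sd = c(sd(a), sd(b)))
  f <- anova_from_summaries(s)$statistic
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(f, unname(tt$statistic)^2, tolerance = 1e-10)
  # identical means give F = 0
  s0 <- tibble::tibble(n = c(10, 10), mean = c(1, 1), sd = c(1, 2))
  expect_equal(anova_from_summaries(s0)$statistic, 0)
  expect_error(anova_from_summaries(tibble::tibble(n = c(5, 5), mean = 0:1, sd = c(-1, 1))),
               "non-negative")
})

test_that("chi-square independence matches hand computations and invariances", {
  out <- chi_square_independence(matrix(c(10, 0, 0, 10), 2, byrow = TRUE))
  expect_equal(out$statistic, 20)
  expect_equal(out$df, 1)
  # margin-proportional tables give exactly zero
  t0 <- outer(c(30, 20), c(0.4, 0.6)) |> round()
  expect_equal(chi_square_independence(t0)$statistic, 0, tolerance = 1e-12)
  # permutation invariance
  tab <- matrix(c(11, 22, 16, 5, 13, 7), 3, byrow = TRUE)
  expect_equal(chi_square_independence(tab)$statistic,
               chi_square_independence(tab[c(3, 1, 2), c(2, 1)])$statistic,
               tolerance = 1e-12)
  expect_error(chi_square_independence(matrix(c(0, 0, 3, 4), 2)), "margin")
})

test_that("ANCOVA reduces to one-way ANOVA without covariate effects", {
  set.seed(31)
  d <- tibble::tibble(
    y = c(rnorm(20, 0), rnorm(20, 1), rnorm(20, 2)),
    g = factor(rep(c("a", "b", "c"), each = 20))
  )
  fit <- fit_ancova(d, "y", "g")
  ref <- anova(lm(y ~ g, data = d))
  expect_equal(fit$statistic, ref$`F value`[1], tolerance = 1e-10)
  expect_equal(fit$partial_eta2,
               ref$`Sum Sq`[1] / sum(ref$`Sum Sq`), tolerance = 1e-10)
  # outcome explained exactly by a covariate: group F ~ 0
  d$x <- rnorm(60)
  d$y2 <- 3 * d$x
  fit2 <- fit_ancova(d, "y2", "g", "x")
  expect_lt(abs(fit2$statistic), 1e-8)
})

test_that("ANCOVA group F and adjusted means match independent oracles", {
  set.seed(32)
  n <- 60
  d <- tibble::tibble(
    g = factor(sample(c("a", "b", "c"), n, replace = TRUE)),
    age = rnorm(n, 35, 10),
    gender = sample(c("male", "female"), n, replace = TRUE),
    education_years = rnorm(n, 15, 2)
  )
  shift <- c(a = 0, b = 1.5, c = 2.5)
  d$y <- shift[as.character(d$g)] + 0.1 * d$age + rnorm(n)
  fit <- fit_ancova(d, "y", "g", c("age", "gender", "education_years"))
  d2 <- d; d2$gender01 <- as.numeric(factor(d2$gender)) - 1
  full <- lm(y ~ g + age + gender01 + education_years, data = d2)
  red <- lm(y ~ age + gender01 + education_years, data = d2)
  ref <- anova(red, full)
  expect_equal(fit$statistic, ref$F[2], tolerance = 1e-8)
  expect_equal(fit$df1, 2)
  expect_equal(fit$df2, n - 3 - 3)
  expect_equal(fit$partial_eta2,
               fit$df1 * fit$statistic / (fit$df1 * fit$statistic + fit$df2),
               tolerance = 1e-12)
  skip_if_not_installed("emmeans")
  # cross-check against emmeans at the covariate sample means
  em <- emmeans::emmeans(full, "g", cov.keep = character(0))
  expect_equal(fit$adjusted_means$adjusted_mean,
               summary(em)$emmean, tolerance = 1e-8)
  # collinear covariate is reported by name
  d$dup <- d$age
  expect_error(fit_ancova(d, "y", "g", c("age", "dup")), "collinear")
})

test_that("Bonferroni subsets chain non-significant pairs into shared letters", {
  set.seed(33)
  make_fit <- function(means, n = 25, sd = 1) {
    d <- tibble::tibble(
      y = c(rnorm(n, means[1], sd), rnorm(n, means[2], sd), rnorm(n, means[3], sd)),
      g = factor(rep(c("a", "b", "c"), each = n))
    )
    fit_ancova(d, "y", "g")
  }
  sep <- bonferroni_subsets(make_fit(c(0, 4, 8)))
  expect_equal(sort(sep$letters$letters), c("a", "b", "c"))
  expect_true(all(sep$pairwise$p_adjusted < 0.05))
  same <- bonferroni_subsets(make_fit(c(0, 0.05, 0.1)))
  expect_equal(same$letters$letters, rep("a", 3))
  # one close pair shares a letter, the distant group stands alone
  mix <- bonferroni_subsets(make_fit(c(0, 0.2, 6)))
  lets <- setNames(mix$letters$letters, mix$letters$group)
  expect_equal(lets[["a"]], lets[["b"]])
  expect_false(lets[["c"]] %in% lets[c("a", "b")])
  # adjusted p-values are raw p times number of pairs, capped at 1
  expect_true(all(mix$pairwise$p_adjusted <=
                    pmin(1, mix$pairwise$p_value * 3) + 1e-12))
})

test_that("partial correlation matches the precision-matrix oracle", {
  set.seed(41)
  n <- 40
  covs <- tibble::tibble(z1 = rnorm(n), z2 = rnorm(n))
  x <- 0.5 * covs$z1 + rnorm(n)
  y <- -0.3 * covs$z1 + 0.4 * x + rnorm(n)
  mine <- partial_correlation(x, y, covs)
  expect_equal(mine$estimate, oracle_partial_cor(x, y, covs), tolerance = 1e-10)
  expect_equal(mine$df, n - 2 - 2)
  # no covariates: plain Pearson r
  p0 <- partial_correlation(x, y)
  expect_equal(p0$estimate, cor(x, y), tolerance = 1e-12)
  expect_equal(p0$p_value, cor.test(x, y)$p.value, tolerance = 1e-10)
  # orthogonal covariates leave r unchanged
  set.seed(42)
  xo <- rnorm(200); yo <- 0.5 * xo + rnorm(200)
  zo <- resid(lm(rnorm(200) ~ xo + yo))
  expect_equal(partial_correlation(xo, yo, data.frame(z = zo))$estimate,
               cor(xo, yo), tolerance = 1e-6)
  # y identical to x
  expect_equal(partial_correlation(xo, xo, data.frame(z = zo))$estimate, 1)
  # constant residuals are undefined
  expect_true(is.na(partial_correlation(covs$z1, y, covs)$estimate))
})

test_that("noncentral-F power is correct and sample size search is monotone", {
  # against the quadrature oracle
  for (n in c(30, 66, 100)) {
    expect_equal(ancova_power(n, f = 0.5, alpha = 0.05, k_groups = 3, n_covariates = 3),
                 oracle_ncf_power(n, 0.5, 0.05, 3, 3), tolerance = 1e-8)
  }
  n_med <- required_n_ancova(f = 0.25, alpha = 0.05, power = 0.80,
                             k_groups = 3, n_covariates = 0)
  expect_equal(ancova_power(n_med, 0.25, 0.05, 3, 0) >= 0.80, TRUE)
  expect_lt(ancova_power(n_med - 1, 0.25, 0.05, 3, 0), 0.80)
  expect_equal(oracle_ncf_power(n_med, 0.25, 0.05, 3, 0) >= 0.80, TRUE)
  # power rises with N; required N rises with target power
  pw <- vapply(seq(20, 200, by = 20), ancova_power, numeric(1),
               f = 0.3, alpha = 0.05, k_groups = 3, n_covariates = 3)
  expect_true(all(diff(pw) > 0))
  expect_lte(required_n_ancova(0.5, 0.05, 0.80, 3, 3),
             required_n_ancova(0.5, 0.05, 0.95, 3, 3))
  expect_error(required_n_ancova(0.01, 0.05, 0.999, 3, 3, n_max = 500),
               "unattainable")
})
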