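test_that("machine intensities bin by rounding half away from zero with clamping", {
  expect_equal(bin_machine_intensity(c(1.5, 5.7, 0.49, 0.5, 2.49, 4.5)),
               c(2L, 5L, 0L, 1L, 2L, 5L))
  expect_error(bin_machine_intensity(-0.1), "non-negative")
})

test_that("percent agreement is the raw matching proportion", {
  expect_equal(percent_agreement(rep(2, 17), rep(2, 17)), 100)
  h <- c(rep(0, 43), 1, 0); m <- c(rep(0, 43), 0, 1)
  expect_equal(percent_agreement(h, m), 100 * 43 / 45)
  expect_equal(percent_agreement(rep(0, 10), rep(1, 10)), 0)
  expect_error(percent_agreement(numeric(0), numeric(0)), "at least 1")
})

test_that("Cohen's kappa matches hand-computed and sparse examples", {
  p <- pairs_from_counts(matrix(c(20, 5, 10, 15), 2, byrow = TRUE))
  expect_equal(cohens_kappa(p$human, p$machine), 0.4)
  # sparsity paradox: near-perfect raw agreement, negative kappa
  h <- c(rep(0, 43), 1, 0); m <- c(rep(0, 43), 0, 1)
  k <- cohens_kappa(h, m)
  expect_equal(k, -0.02273, tolerance = 1e-3)
  expect_lt(k, 0)
  # both raters constant: chance agreement is 1, kappa undefined
  expect_true(is.na(cohens_kappa(rep(0, 5), rep(0, 5))))
  expect_equal(cohens_kappa(c(0, 1, 2), c(0, 1, 2)), 1)
})

test_that("Gwet's AC1 matches hand-computed examples and resists sparsity", {
  p <- pairs_from_counts(matrix(c(20, 5, 10, 15), 2, byrow = TRUE))
  expect_equal(gwets_ac1(p$human, p$machine, categories = 0:1), 0.406, tolerance = 1e-3)
  h <- c(rep(0, 43), 1, 0); m <- c(rep(0, 43), 0, 1)
  expect_equal(gwets_ac1(h, m, categories = 0:1), 0.954, tolerance = 1e-3)
  expect_gt(gwets_ac1(h, m, categories = 0:1), cohens_kappa(h, m))
  expect_equal(gwets_ac1(c(0, 1, 2, 3), c(0, 1, 2, 3)), 1)
})

test_that("ordinal alpha handles the canonical special cases", {
  expect_equal(kripp_alpha_ordinal(c(0, 1, 2, 3), c(0, 1, 2, 3)), 1)
  # with exactly two observed adjacent values the ordinal metric is constant,
  # so ordinal alpha equals nominal alpha (here computed by the oracle)
  set.seed(3)
  h <- rbinom(20, 1, 0.4); m <- rbinom(20, 1, 0.4)
  expect_equal(kripp_alpha_ordinal(h, m), oracle_alpha_ordinal(h, m), tolerance = 1e-12)
  # constant data: no expected disagreement
  expect_true(is.na(kripp_alpha_ordinal(rep(2, 6), rep(2, 6))))
  # 6-unit toy set with one disagreement, against the brute-force oracle
  h6 <- c(0, 0, 1, 2, 3, 3); m6 <- c(0, 0, 1, 2, 3, 2)
  expect_equal(kripp_alpha_ordinal(h6, m6), oracle_alpha_ordinal(h6, m6),
               tolerance = 1e-12)
})

test_that("ICC(3,1) matches the ANOVA oracle and its shift-invariance property", {
  h <- c(1, 2, 3, 4, 5, 2, 0)
  expect_equal(icc31(h, h), 1)
  expect_equal(icc31(h, h + 1, "consistency"), 1)
  expect_lt(icc31(h, h + 1, "absolute"), 1)
  set.seed(11)
  for (i in 1:20) {
    a <- rnorm(10); b <- 0.8 * a + rnorm(10, sd = 0.5)
    expect_equal(icc31(a, b, "consistency"), oracle_icc(a, b, "consistency"),
                 tolerance = 1e-10)
    expect_equal(icc31(a, b, "absolute"), oracle_icc(a, b, "absolute"),
                 tolerance = 1e-10)
  }
  expect_true(is.na(icc31(rep(1, 5), rep(1, 5))))
})

test_that("all four chance-corrected indices match oracles on random instances", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(5:30, 1)
    prob <- c(0.6, 0.2, 0.1, 0.05, 0.03, 0.02)
    h <- sample(0:5, n, replace = TRUE, prob = prob)
    m <- ifelse(runif(n) < 0.6, h, sample(0:5, n, replace = TRUE, prob = prob))
    expect_equal(cohens_kappa(h, m), oracle_kappa(h, m), tolerance = 1e-10)
    expect_equal(gwets_ac1(h, m), oracle_ac1(h, m), tolerance = 1e-10)
    expect_equal(kripp_alpha_ordinal(h, m), oracle_alpha_ordinal(h, m),
                 tolerance = 1e-10)
    expect_equal(icc31(h, m), oracle_icc(h, m), tolerance = 1e-10)
  }
})

test_that("kappa and AC1 never exceed observed agreement", {
  set.seed(55)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    h <- sample(0:5, n, replace = TRUE, prob = c(0.7, 0.1, 0.1, 0.05, 0.03, 0.02))
    m <- ifelse(runif(n) < 0.7, h, sample(0:5, n, replace = TRUE))
    po <- percent_agreement(h, m) / 100
    k <- cohens_kappa(h, m); a1 <- gwets_ac1(h, m)
    if (!is.na(k)) expect_lte(k, po + 1e-12)
    if (!is.na(a1)) expect_lte(a1, po + 1e-12)
  }
})

test_that("the agreement panel behaves on identical and shifted codings", {
  h <- c(0, 0, 1, 3, 2, 0, 4)
  p <- agreement_panel(h, h)
  expect_equal(unname(unlist(p)), c(100, 1, 1, 1, 1))
  # kappa is bounded by raw agreement on any panel
  set.seed(9)
  m <- pmin(5, pmax(0, h + rnorm(7, sd = 0.6)))
  p2 <- agreement_panel(h, m)
  if (!is.na(p2$kappa)) expect_lte(p2$kappa, p2$percent_agreement / 100)
})

test_that("group_mean_panel aggregates with undefined-exclusion and dash cells", {
  groups <- tibble::tibble(
    participant_id = c("P1", "P2", "P3"),
    bp_group = factor(c("normotensive", "normotensive", "prehypertensive"))
  )
  h <- c(0, 1, 2, 0)
  panels <- tibble::tibble(
    participant_id = c("P1", "P2"),
    intended = factor(c("happiness", "happiness"), levels = facedamp:::EMOTIONS),
    percent_agreement = c(100, 80), kappa = c(1, NA),
    ac1 = c(1, 0.8), alpha = c(1, 0.7), icc = c(1, 0.9)
  )
  out <- group_mean_panel(panels, groups)
  cell <- out[out$bp_group == "normotensive" & out$emotion == "happiness", ]
  expect_equal(cell$n, 2L)
  expect_equal(cell$percent_agreement_mean, 90)
  expect_equal(cell$kappa_mean, 1)           # NA panel excluded from the mean
  expect_equal(cell$kappa_n_undefined, 1L)   # ... and counted
  # a cell with no retained trials stays as an undefined marker
  empty <- out[out$bp_group == "prehypertensive" & out$emotion == "fear", ]
  expect_equal(empty$n, 0L)
  expect_true(is.na(empty$percent_agreement_mean))
  # single-trial cells report SD NA with n = 1 visible
  single <- tibble::tibble(
    participant_id = "P3",
    intended = factor("anger", levels = facedamp:::EMOTIONS),
    percent_agreement = 90, kappa = 0.5, ac1 = 0.6, alpha = 0.55, icc = 0.5
  )
  out2 <- group_mean_panel(single, groups)
  one <- out2[out2$bp_group == "prehypertensive" & out2$emotion == "anger", ]
  expect_equal(one$n, 1L)
  expect_equal(one$kappa_mean, 0.5)
})

test_that("benchmark bands follow the published cut-points", {
  expect_equal(benchmark_agreement(0.68, "icc"), "moderate")
  expect_equal(benchmark_agreement(0.45, "icc"), "poor")
  expect_equal(benchmark_agreement(0.92, "icc"), "excellent")
  expect_equal(benchmark_agreement(0.81, "kappa"), "strong")
  expect_equal(benchmark_agreement(0.60, "kappa"), "weak")
  expect_equal(benchmark_agreement(0.7, "ac1"), "acceptable")
  expect_equal(benchmark_agreement(0.667, "alpha"), "unacceptable")
  expect_equal(benchmark_agreement(0.67, "alpha"), "acceptable")
  expect_equal(benchmark_agreement(0.85, "alpha"), "good")
  expect_error(benchmark_agreement(0.5, "rho"), "arg")
  expect_error(benchmark_agreement(1.2, "icc"), "exceed")
})
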