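#' One-way ANOVA from per-group summary statistics
#'
#' Recovers the exact one-way ANOVA F statistic from (n, mean, SD) triples
#' via the standard decomposition `SSB = sum n_i (m_i - m.)^2`,
#' `SSW = sum (n_i - 1) s_i^2`, which lets published demographic tables be
#' re-tested without the raw data.
#'
#' @param summaries Data frame with columns `n`, `mean`, `sd` (one row per
#'   group; an optional `group` column is carried through).
#' @return One-row tibble: `statistic` (F), `df1`, `df2`, `p_value`.
#' @export
#' @examples
#' anova_from_summaries(tibble::tibble(
#'   n = c(33, 21, 20), mean = c(24.42, 30.10, 40.25), sd = c(6.73, 9.88, 13.47)
#' ))
anova_from_summaries <- function(summaries) {
  stopifnot(all(c("n", "mean", "sd") %in% names(summaries)))
  n <- summaries$n; m <- summaries$mean; s <- summaries$sd
  if (length(n) < 2) stop("need at least two groups", call. = FALSE)
  if (any(n < 2)) stop("each group needs n >= 2", call. = FALSE)
  if (any(s < 0)) stop("standard deviations must be non-negative", call. = FALSE)
  k <- length(n); N <- sum(n)
  gm <- sum(n * m) / N
  ssb <- sum(n * (m - gm)^2)
  ssw <- sum((n - 1) * s^2)
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  tibble::tibble(statistic = f, df1 = k - 1, df2 = N - k,
                 p_value = pf(f, k - 1, N - k, lower.tail = FALSE))
}

#' Pearson chi-square test of independence
#'
#' Classic Pearson statistic on an R x C contingency table, without
#' continuity correction.
#'
#' @param counts Matrix (or data frame) of non-negative counts.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_square_independence(matrix(c(11, 22, 16, 5, 13, 7), 3, 2, byrow = TRUE))
chi_square_independence <- function(counts) {
  counts <- as.matrix(counts)
  if (sum(counts) <= 0) stop("table total must be positive", call. = FALSE)
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("every row and column margin must be positive", call. = FALSE)
  }
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  tibble::tibble(statistic = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value))
}

#' One-way ANCOVA with partial eta squared and adjusted means
#'
#' Fits the classic covariance model `outcome ~ group + covariates` (no
#' group x covariate interactions, so Type II and III group tests coincide)
#' by least squares; the group effect is tested by comparing the residual
#' sums of squares of the full and covariates-only models. Character or
#' factor covariates with two levels (e.g. gender) enter as 0/1 indicators.
#' Adjusted group means are predictions at the sample means of the
#' covariates.
#'
#' @param data Data frame, one row per subject.
#' @param outcome,group Column names of the response and the grouping factor.
#' @param covariates Character vector of covariate column names (may be
#'   empty).
#' @return An object of class `facedamp_ancova` with fields `statistic`,
#'   `df1`, `df2`, `p_value`, `partial_eta2`, `adjusted_means`, and the
#'   underlying `lm` fit. `statistic` is `NA` when the outcome carries no
#'   residual variance.
#' @export
fit_ancova <- function(data, outcome, group, covariates = character()) {
  stopifnot(is.data.frame(data))
  need <- c(outcome, group, covariates)
  missing <- setdiff(need, names(data))
  if (length(missing)) stop("missing column(s): ", toString(missing), call. = FALSE)
  dat <- dplyr::as_tibble(data[need])
  if (!all(complete.cases(dat))) stop("ANCOVA input contains missing values", call. = FALSE)
  y <- as.numeric(dat[[outcome]])
  g <- droplevels(factor(dat[[group]]))
  k <- nlevels(g)
  if (k < 2) stop("need at least two groups", call. = FALSE)

  covs <- dat[covariates]
  covs[] <- lapply(covs, function(x) {
    if (is.numeric(x)) return(x)
    f <- factor(x)
    if (nlevels(f) != 2) stop("non-numeric covariates must have two levels", call. = FALSE)
    as.numeric(f) - 1
  })
  X_cov <- if (length(covariates)) as.matrix(covs) else NULL

  df_full <- data.frame(.y = y, .g = g, covs, check.names = FALSE)
  rhs <- paste(c(".g", sprintf("`%s`", covariates)), collapse = " + ")
  fit_full <- lm(stats::as.formula(paste(".y ~", rhs)), data = df_full)
  if (fit_full$rank < ncol(model.matrix(fit_full))) {
    mm <- model.matrix(fit_full)
    aliased <- colnames(mm)[is.na(coef(fit_full))]
    stop("rank-deficient ANCOVA design; collinear column(s): ",
         toString(aliased), call. = FALSE)
  }
  rhs_red <- if (length(covariates)) paste(sprintf("`%s`", covariates), collapse = " + ") else "1"
  fit_red <- lm(stats::as.formula(paste(".y ~", rhs_red)), data = df_full)

  sse_full <- sum(resid(fit_full)^2)
  sse_red <- sum(resid(fit_red)^2)
  ss_group <- sse_red - sse_full
  df1 <- k - 1
  df2 <- length(y) - k - length(covariates)
  tol <- 1e-12 * (sum(y^2) + 1)
  f <- if (sse_full <= tol) {
    # saturated fit: no residual variance left to test against
    if (ss_group <= tol) 0 else Inf
  } else {
    (ss_group / df1) / (sse_full / df2)
  }

  # adjusted means: predictions at the covariate sample means
  newdata <- data.frame(.g = factor(levels(g), levels = levels(g)))
  for (cv in covariates) newdata[[cv]] <- mean(covs[[cv]])
  pred <- suppressWarnings(predict(fit_full, newdata = newdata, se.fit = TRUE))
  adjusted <- tibble::tibble(
    group = levels(g),
    n = as.integer(table(g)),
    raw_mean = as.numeric(tapply(y, g, mean)),
    adjusted_mean = as.numeric(pred$fit),
    se = as.numeric(pred$se.fit)
  )

  structure(
    list(statistic = f, df1 = df1, df2 = df2,
         p_value = if (is.na(f)) NA_real_ else pf(f, df1, df2, lower.tail = FALSE),
         partial_eta2 = if (is.na(f)) NA_real_ else if (ss_group + sse_full <= tol) 0
           else ss_group / (ss_group + sse_full),
         adjusted_means = adjusted,
         outcome = outcome, group = group, covariates = covariates,
         model = fit_full, n = length(y)),
    class = "facedamp_ancova"
  )
}

#' @export
print.facedamp_ancova <- function(x, ...) {
  cat(sprintf("ANCOVA: %s ~ %s%s\n", x$outcome, x$group,
              if (length(x$covariates)) paste0(" + ", paste(x$covariates, collapse = " + ")) else ""))
  cat(sprintf("  F(%d, %d) = %.3f, p = %.4g, partial eta^2 = %.3f\n",
              x$df1, x$df2, x$statistic, x$p_value, x$partial_eta2))
  print(x$adjusted_means)
  invisible(x)
}

#' @export
tidy.facedamp_ancova <- function(x, ...) x$adjusted_means

#' @export
glance.facedamp_ancova <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
                 p_value = x$p_value, partial_eta2 = x$partial_eta2, n = x$n)
}

#' Bonferroni-adjusted pairwise comparisons with subset letters
#'
#' All pairwise covariate-adjusted group comparisons from a fitted ANCOVA;
#' each p-value is multiplied by the number of pairs (capped at 1). Subset
#' letters are assigned by chaining: with groups ordered by adjusted mean,
#' every maximal run whose pairwise adjusted p-values are all at or above
#' `alpha` shares a letter, so groups with a common letter do not differ
#' significantly.
#'
#' @param fit A `facedamp_ancova` object.
#' @param alpha Significance level for the subset chaining (default 0.05).
#' @return List with `pairwise` (tibble: groups, estimate, se, statistic,
#'   df, p_value, p_adjusted) and `letters` (tibble: group, adjusted_mean,
#'   letters).
#' @export
bonferroni_subsets <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "facedamp_ancova"))
  adj <- fit$adjusted_means
  groups <- adj$group
  k <- length(groups)
  V <- suppressWarnings(vcov(fit$model))  # silence perfect-fit chatter on saturated cells
  # adjusted-mean differences reduce to group-dummy coefficient contrasts
  mm_labels <- names(coef(fit$model))
  coef_of <- function(gr) {
    lab <- paste0(".g", gr)
    v <- numeric(length(mm_labels)); names(v) <- mm_labels
    if (lab %in% mm_labels) v[lab] <- 1
    v
  }
  prs <- combn(groups, 2, simplify = FALSE)
  rows <- purrr::map(prs, function(pr) {
    L <- coef_of(pr[1]) - coef_of(pr[2])
    est <- sum(L * coef(fit$model))
    se <- sqrt(drop(t(L) %*% V %*% L))
    if (se < 1e-10) {
      # saturated cell: identical outcomes are indistinguishable
      tval <- if (abs(est) < 1e-10) 0 else sign(est) * Inf
      p <- if (abs(est) < 1e-10) 1 else 0
    } else {
      tval <- est / se
      p <- 2 * pt(-abs(tval), df = fit$df2)
    }
    tibble::tibble(group1 = pr[1], group2 = pr[2], estimate = est, se = se,
                   statistic = tval, df = fit$df2, p_value = p,
                   p_adjusted = min(1, p * length(prs)))
  })
  pairwise <- dplyr::bind_rows(rows)

  ord <- order(adj$adjusted_mean)
  sorted <- groups[ord]
  ns <- function(a, b) {
    row <- pairwise[(pairwise$group1 == a & pairwise$group2 == b) |
                    (pairwise$group1 == b & pairwise$group2 == a), ]
    row$p_adjusted >= alpha
  }
  # maximal intervals of the sorted groups whose pairs are all non-significant
  intervals <- list()
  i <- 1
  while (i <= k) {
    j <- i
    while (j < k && all(vapply(i:j, function(a) ns(sorted[a], sorted[j + 1]), logical(1)))) {
      j <- j + 1
    }
    intervals[[length(intervals) + 1]] <- c(i, j)
    i <- i + 1
  }
  # drop intervals nested in another
  keep <- vapply(seq_along(intervals), function(a) {
    !any(vapply(seq_along(intervals), function(b) {
      b != a && intervals[[b]][1] <= intervals[[a]][1] &&
        intervals[[b]][2] >= intervals[[a]][2]
    }, logical(1)))
  }, logical(1))
  intervals <- intervals[keep]
  letter_of <- setNames(rep("", k), sorted)
  for (ii in seq_along(intervals)) {
    rng <- intervals[[ii]]
    for (g in sorted[rng[1]:rng[2]]) {
      letter_of[g] <- paste0(letter_of[g], letters[ii])
    }
  }
  letters_tbl <- tibble::tibble(
    group = groups,
    adjusted_mean = adj$adjusted_mean,
    letters = unname(letter_of[groups])
  )
  list(pairwise = pairwise, letters = letters_tbl)
}

#' Partial correlation controlling for covariates
#'
#' Residualises `x` and `y` on the covariates (plus intercept) by least
#' squares and correlates the residuals. The two-tailed p-value comes from
#' `t = r sqrt(df / (1 - r^2))` with `df = n - 2 - k` where `k` is the
#' number of covariates. With no covariates this is the plain Pearson
#' correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional numeric matrix / data frame of covariates
#'   (two-level factors are accepted and coded 0/1).
#' @return One-row tibble: `estimate` (r), `df`, `statistic` (t),
#'   `p_value`; all `NA` when either residual vector is constant.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (is.null(covariates)) {
    Z <- matrix(1, n, 1)
    k <- 0L
  } else {
    cv <- as.data.frame(covariates)
    cv[] <- lapply(cv, function(col) {
      if (is.numeric(col)) return(col)
      f <- factor(col)
      if (nlevels(f) != 2) stop("non-numeric covariates must have two levels", call. = FALSE)
      as.numeric(f) - 1
    })
    Z <- cbind(1, as.matrix(cv))
    k <- ncol(Z) - 1L
  }
  if (n <= k + 2) stop("need n > k + 2 observations", call. = FALSE)
  rx <- stats::lm.fit(Z, x)$residuals
  ry <- stats::lm.fit(Z, y)$residuals
  if (sd(rx) < 1e-12 || sd(ry) < 1e-12) {
    return(tibble::tibble(estimate = NA_real_, df = NA_integer_,
                          statistic = NA_real_, p_value = NA_real_))
  }
  r <- stats::cor(rx, ry)
  df <- n - 2L - k
  tval <- r * sqrt(df / (1 - r^2))
  tibble::tibble(estimate = r, df = df, statistic = tval,
                 p_value = 2 * pt(-abs(tval), df))
}

#' Statistical power of the ANCOVA group test
#'
#' Power of the fixed-effects one-way ANCOVA F test of the group factor via
#' the noncentral F distribution: with `k` groups, `c` covariates, total
#' sample size `n` and Cohen's effect size `f`, power is
#' `P(F'(k - 1, n - k - c, lambda = f^2 n) > F_crit(alpha))`.
#'
#' @param n Total sample size.
#' @param f Cohen's effect size f (> 0).
#' @param alpha Type-I error rate.
#' @param k_groups Number of groups.
#' @param n_covariates Number of covariates.
#' @return Power in \[0, 1\].
#' @export
#' @examples
#' ancova_power(66, f = 0.5, alpha = 0.05, k_groups = 3, n_covariates = 3)
ancova_power <- function(n, f, alpha = 0.05, k_groups = 3, n_covariates = 0) {
  stopifnot(f > 0, alpha > 0, alpha < 1)
  df1 <- k_groups - 1
  df2 <- n - k_groups - n_covariates
  if (df2 < 1) return(0)
  crit <- qf(1 - alpha, df1, df2)
  pf(crit, df1, df2, ncp = f^2 * n, lower.tail = FALSE)
}

#' A priori total sample size for the ANCOVA group test
#'
#' Smallest total N whose noncentral-F power reaches the requested level.
#'
#' @inheritParams ancova_power
#' @param power Target power (0 < power < 1).
#' @param n_max Search bound; exceeding it raises an error.
#' @return Integer total sample size.
#' @export
#' @examples
#' required_n_ancova(f = 0.5, alpha = 0.05, power = 0.95,
#'                   k_groups = 3, n_covariates = 3)
required_n_ancova <- function(f, alpha = 0.05, power = 0.95, k_groups = 3,
                              n_covariates = 0, n_max = 100000) {
  stopifnot(power > 0, power < 1)
  n <- k_groups + n_covariates + 2  # smallest n with df2 >= 2
  while (n <= n_max) {
    if (ancova_power(n, f, alpha, k_groups, n_covariates) >= power) {
      return(as.integer(n))
    }
    n <- n + 1
  }
  stop("requested power unattainable within n_max = ", n_max, call. = FALSE)
}
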