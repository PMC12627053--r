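# Independent brute-force oracles for the agreement indices. These are
# deliberately written as plain loops over the raw definitions, sharing no
# code with the package implementations.

# expand a contingency matrix (rows = rater 1 category, cols = rater 2
# category, dimnames give category values) into paired rating vectors
pairs_from_counts <- function(counts, values = seq_len(nrow(counts)) - 1) {
  h <- c(); m <- c()
  for (i in seq_len(nrow(counts))) {
    for (j in seq_len(ncol(counts))) {
      k <- counts[i, j]
      h <- c(h, rep(values[i], k))
      m <- c(m, rep(values[j], k))
    }
  }
  list(human = h, machine = m)
}

oracle_kappa <- function(h, m) {
  n <- length(h)
  po <- 0
  for (i in seq_len(n)) po <- po + (h[i] == m[i])
  po <- po / n
  cats <- sort(unique(c(h, m)))
  pe <- 0
  for (q in cats) pe <- pe + (sum(h == q) / n) * (sum(m == q) / n)
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

oracle_ac1 <- function(h, m, categories = 0:5) {
  n <- length(h)
  po <- sum(h == m) / n
  Q <- length(categories)
  pe <- 0
  for (q in categories) {
    piq <- (sum(h == q) / n + sum(m == q) / n) / 2
    pe <- pe + piq * (1 - piq)
  }
  pe <- pe / (Q - 1)
  if (abs(1 - pe) < 1e-12) return(NA_real_)
  (po - pe) / (1 - pe)
}

# ordinal alpha by looping over every ordered pair of pooled rating tokens
oracle_alpha_ordinal <- function(h, m) {
  pooled <- c(h, m)
  cats <- sort(unique(pooled))
  if (length(cats) < 2) return(NA_real_)
  n_g <- sapply(cats, function(v) sum(pooled == v))
  d2 <- function(a, b) {
    if (a == b) return(0)
    ia <- which(cats == a); ib <- which(cats == b)
    lo <- min(ia, ib); hi <- max(ia, ib)
    (sum(n_g[lo:hi]) - (n_g[ia] + n_g[ib]) / 2)^2
  }
  n <- length(h)
  Do <- 0
  for (u in seq_len(n)) Do <- Do + 2 * d2(h[u], m[u])  # both ordered pairs
  Do <- Do / (2 * n)
  De <- 0
  for (a in seq_along(pooled)) {
    for (b in seq_along(pooled)) {
      if (a != b) De <- De + d2(pooled[a], pooled[b])
    }
  }
  De <- De / (2 * n * (2 * n - 1))
  if (De == 0) return(NA_real_)
  1 - Do / De
}

# ICC(3,1) through R's own two-way ANOVA table
oracle_icc <- function(h, m, variant = "consistency") {
  n <- length(h)
  dat <- data.frame(
    y = c(h, m),
    unit = factor(rep(seq_len(n), 2)),
    rater = factor(rep(1:2, each = n))
  )
  tab <- suppressWarnings(anova(lm(y ~ unit + rater, data = dat)))
  MSR <- tab["unit", "Mean Sq"]
  MSC <- tab["rater", "Mean Sq"]
  MSE <- tab["Residuals", "Mean Sq"]
  if (MSR + MSE < 1e-14) return(NA_real_)
  if (variant == "consistency") (MSR - MSE) / (MSR + MSE)
  else (MSR - MSE) / (MSR + MSE + 2 * (MSC - MSE) / n)
}

# partial correlation through the precision (inverse correlation) matrix
oracle_partial_cor <- function(x, y, covs) {
  R <- stats::cor(cbind(x, y, as.matrix(covs)))
  P <- solve(R)
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}

# noncentral-F tail probability by quadrature over the denominator chi-square
oracle_ncf_power <- function(n, f, alpha, k, c) {
  df1 <- k - 1; df2 <- n - k - c
  crit <- qf(1 - alpha, df1, df2)
  integrand <- function(u) {
    pchisq(crit * df1 * u / df2, df = df1, ncp = f^2 * n, lower.tail = FALSE) *
      dchisq(u, df = df2)
  }
  integrate(integrand, 0, Inf, rel.tol = 1e-10)$value
}

small_config <- function(seed = 1, ...) {
  synth_config(
    group_sizes = c(normotensive = 8, prehypertensive = 6, hypertensive_stage1 = 6),
    seed = seed, ...
  )
}
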