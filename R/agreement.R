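#' Inter-rater agreement indices for paired AU ratings
#'
#' The five-index panel used to compare the human coder with the automated
#' coder at the Action-Unit level. All functions take two equal-length
#' vectors of ratings, one element per AU of the comparison set. The
#' categorical indices (`percent_agreement`, `cohens_kappa`, `gwets_ac1`,
#' `kripp_alpha_ordinal`) expect both vectors on the 0-5 ordinal scale (bin
#' machine values first with [bin_machine_intensity()]); `icc31` accepts
#' continuous values. Indices that are undefined on the input (e.g. both
#' raters constant, so chance agreement is 1) return `NA` rather than a
#' numeric value, and are excluded from group means by [group_mean_panel()].
#'
#' @param human,machine Equal-length rating vectors.
#' @param categories The full category scale for Gwet's AC1 (all scale
#'   points, not only the observed ones). Default `0:5`.
#' @name agreement_indices
NULL

check_pairs <- function(human, machine, min_n = 1) {
  if (length(human) != length(machine)) {
    stop("`human` and `machine` must have the same length", call. = FALSE)
  }
  if (length(human) < min_n) {
    stop("need at least ", min_n, " rating pair(s)", call. = FALSE)
  }
  invisible(TRUE)
}

#' @rdname agreement_indices
#' @return `percent_agreement()`: percentage in \[0, 100\].
#' @export
#' @examples
#' percent_agreement(c(0, 0, 1, 2), c(0, 0, 1, 1))
percent_agreement <- function(human, machine) {
  check_pairs(human, machine)
  100 * mean(human == machine)
}

#' @rdname agreement_indices
#' @return `cohens_kappa()`: chance-corrected agreement using each rater's
#'   observed marginal distribution; `NA` when both raters are constant.
#' @export
cohens_kappa <- function(human, machine) {
  check_pairs(human, machine)
  cats <- sort(unique(c(human, machine)))
  p1 <- vapply(cats, function(q) mean(human == q), numeric(1))
  p2 <- vapply(cats, function(q) mean(machine == q), numeric(1))
  p_o <- mean(human == machine)
  p_e <- sum(p1 * p2)
  if (abs(1 - p_e) < 1e-12) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' @rdname agreement_indices
#' @return `gwets_ac1()`: chance-corrected agreement with the mean-marginal
#'   chance term `sum(pi_q (1 - pi_q)) / (Q - 1)` over the full `Q`-category
#'   scale, robust to prevalence imbalance.
#' @export
gwets_ac1 <- function(human, machine, categories = 0:5) {
  check_pairs(human, machine)
  Q <- length(categories)
  if (Q < 2) stop("AC1 needs a scale with at least 2 categories", call. = FALSE)
  pi_q <- vapply(categories,
                 function(q) (mean(human == q) + mean(machine == q)) / 2,
                 numeric(1))
  p_o <- mean(human == machine)
  p_e <- sum(pi_q * (1 - pi_q)) / (Q - 1)
  if (abs(1 - p_e) < 1e-12) return(NA_real_)
  (p_o - p_e) / (1 - p_e)
}

#' @rdname agreement_indices
#' @return `kripp_alpha_ordinal()`: Krippendorff's alpha from the two-rater
#'   coincidence matrix with the ordinal squared-distance metric
#'   `delta^2(c, k) = (sum(n_g, g = c..k) - (n_c + n_k) / 2)^2`; `NA` when
#'   expected disagreement is zero.
#' @export
kripp_alpha_ordinal <- function(human, machine) {
  check_pairs(human, machine, min_n = 2)
  cats <- sort(unique(c(human, machine)))
  K <- length(cats)
  if (K < 2) return(NA_real_)
  h <- match(human, cats)
  m <- match(machine, cats)
  # coincidence matrix: each unit contributes both ordered pairs
  o <- matrix(0, K, K)
  for (u in seq_along(h)) {
    o[h[u], m[u]] <- o[h[u], m[u]] + 1
    o[m[u], h[u]] <- o[m[u], h[u]] + 1
  }
  n_g <- rowSums(o)
  n_tot <- sum(n_g)
  cum <- cumsum(n_g)
  d2 <- matrix(0, K, K)
  for (c in seq_len(K)) {
    for (k in seq_len(K)) {
      if (c == k) next
      lo <- min(c, k); hi <- max(c, k)
      inner <- cum[hi] - if (lo > 1) cum[lo - 1] else 0
      d2[c, k] <- (inner - (n_g[c] + n_g[k]) / 2)^2
    }
  }
  D_o <- sum(o * d2)
  D_e <- sum(outer(n_g, n_g) * d2)
  if (D_e == 0) return(NA_real_)
  1 - (n_tot - 1) * D_o / D_e
}

#' @rdname agreement_indices
#' @param variant `"consistency"` (canonical ICC(3,1)) or `"absolute"`
#'   (penalises a constant shift between raters).
#' @return `icc31()`: single-rater intraclass correlation from the two-way
#'   (units x raters) mean-square decomposition; `NA` when the units carry
#'   no variance.
#' @export
icc31 <- function(human, machine, variant = c("consistency", "absolute")) {
  variant <- match.arg(variant)
  check_pairs(human, machine, min_n = 3)
  X <- cbind(human, machine)
  n <- nrow(X); k <- 2
  grand <- mean(X)
  MSR <- k * sum((rowMeans(X) - grand)^2) / (n - 1)
  MSC <- n * sum((colMeans(X) - grand)^2) / (k - 1)
  SSE <- sum((X - grand)^2) - (n - 1) * MSR - (k - 1) * MSC / 1
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR + MSE < 1e-14) return(NA_real_)
  if (variant == "consistency") {
    (MSR - MSE) / (MSR + MSE)
  } else {
    den <- MSR + MSE + 2 * (MSC - MSE) / n
    if (abs(den) < 1e-14) return(NA_real_)
    (MSR - MSE) / den
  }
}

#' Five-index agreement panel for one paired coding
#'
#' Bins the machine intensities onto the 0-5 scale for the categorical
#' indices; ICC(3,1) uses the unbinned machine values by default since it is
#' defined for continuous ratings.
#'
#' @param human Integer human ratings (0-5), one per AU.
#' @param machine Continuous machine ratings (0-5), one per AU.
#' @param categories Scale for Gwet's AC1.
#' @param icc_variant Passed to [icc31()].
#' @param bin_icc Use binned machine values for the ICC as well.
#' @return One-row tibble: `percent_agreement`, `kappa`, `ac1`, `alpha`,
#'   `icc`.
#' @export
#' @examples
#' agreement_panel(c(0, 0, 2, 3), c(0.1, 0.2, 1.8, 2.6))
agreement_panel <- function(human, machine, categories = 0:5,
                            icc_variant = c("consistency", "absolute"),
                            bin_icc = FALSE) {
  icc_variant <- match.arg(icc_variant)
  binned <- bin_machine_intensity(machine)
  icc_m <- if (bin_icc) binned else machine
  tibble::tibble(
    percent_agreement = percent_agreement(human, binned),
    kappa = cohens_kappa(human, binned),
    ac1 = gwets_ac1(human, binned, categories),
    alpha = kripp_alpha_ordinal(human, binned),
    icc = if (length(human) >= 3) icc31(human, icc_m, icc_variant) else NA_real_
  )
}

#' Per-trial agreement panels
#'
#' Computes [agreement_panel()] for every trial that carries both raters'
#' codings, over the comparison AU set.
#'
#' @param trials Trials tibble from [assemble_trials()] (list-columns
#'   `human` and `machine` holding named AU vectors).
#' @param au_set Comparison AU ids; default the intersection of the AUs
#'   coded by both raters.
#' @inheritParams agreement_panel
#' @return `trials` with the five index columns appended; trials lacking a
#'   machine coding get `NA` panels.
#' @export
trial_panels <- function(trials, au_set = NULL,
                         icc_variant = c("consistency", "absolute"),
                         bin_icc = FALSE) {
  icc_variant <- match.arg(icc_variant)
  stopifnot(all(c("human", "machine") %in% names(trials)))
  panels <- purrr::map2(trials$human, trials$machine, function(h, m) {
    if (is.null(m) || all(is.na(m))) {
      return(tibble::tibble(percent_agreement = NA_real_, kappa = NA_real_,
                            ac1 = NA_real_, alpha = NA_real_, icc = NA_real_))
    }
    aus <- au_set %||% intersect(as.integer(names(h)), as.integer(names(m)))
    key <- as.character(aus)
    agreement_panel(as.numeric(h[key]), as.numeric(m[key]),
                    icc_variant = icc_variant, bin_icc = bin_icc)
  })
  dplyr::bind_cols(dplyr::as_tibble(trials), dplyr::bind_rows(panels))
}

#' Group-level agreement summary (mean and SD per index)
#'
#' Aggregates per-trial panels by BP group and emotion. Undefined panels
#' (`NA`) are excluded from each index's mean with the exclusion count
#' reported per cell; cells with no retained trials keep `NA` means,
#' mirroring the dashes used for empty cells in study reports.
#'
#' @param panels Output of [trial_panels()] (after retention filtering).
#' @param groups Data frame with `participant_id`, `bp_group`.
#' @return Tibble with one row per group x emotion: `n`, then `<index>_mean`,
#'   `<index>_sd`, `<index>_n_undefined` for each of the five indices.
#' @export
group_mean_panel <- function(panels, groups) {
  idx <- c("percent_agreement", "kappa", "ac1", "alpha", "icc")
  dat <- dplyr::inner_join(
    dplyr::as_tibble(panels),
    dplyr::as_tibble(groups[c("participant_id", "bp_group")]),
    by = "participant_id"
  )
  grid_groups <- droplevels(unique(groups$bp_group))
  dat$bp_group <- factor(dat$bp_group, levels = levels(grid_groups))
  dat |>
    dplyr::group_by(bp_group = .data$bp_group, emotion = .data$intended) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(idx),
                    list(mean = ~ if (all(is.na(.x))) NA_real_ else mean(.x, na.rm = TRUE),
                         # single defined value: SD 0 (the n column flags n = 1)
                         sd = ~ {
                           v <- .x[!is.na(.x)]
                           if (!length(v)) NA_real_ else if (length(v) == 1) 0 else sd(v)
                         },
                         n_undefined = ~ sum(is.na(.x)))),
      .groups = "drop"
    ) |>
    tidyr::complete(
      bp_group = grid_groups,
      emotion = factor(EMOTIONS, levels = EMOTIONS),
      fill = list(n = 0L)
    ) |>
    dplyr::arrange(.data$emotion, .data$bp_group)
}

#' Interpret an agreement value against published benchmark bands
#'
#' ICC: below 0.5 poor, 0.5-0.75 moderate, 0.75-0.90 good, above 0.90
#' excellent. Kappa / AC1: at or below 0.60 weak, above 0.60 acceptable,
#' above 0.80 strong. Alpha: at or below 0.667 unacceptable, above 0.667
#' acceptable, above 0.80 good.
#'
#' @param value Agreement value (at most 1).
#' @param metric One of `"icc"`, `"kappa"`, `"ac1"`, `"alpha"`.
#' @return Character label (`NA` for `NA` input).
#' @export
#' @examples
#' benchmark_agreement(0.68, "icc")
benchmark_agreement <- function(value, metric) {
  metric <- match.arg(metric, c("icc", "kappa", "ac1", "alpha"))
  if (any(value > 1, na.rm = TRUE)) stop("agreement values cannot exceed 1", call. = FALSE)
  lab <- switch(metric,
    icc = function(v) if (v < 0.5) "poor" else if (v < 0.75) "moderate"
      else if (v <= 0.90) "good" else "excellent",
    kappa = ,
    ac1 = function(v) if (v <= 0.60) "weak" else if (v <= 0.80) "acceptable" else "strong",
    alpha = function(v) if (v <= 0.667) "unacceptable" else if (v <= 0.80) "acceptable" else "good"
  )
  vapply(value, function(v) if (is.na(v)) NA_character_ else lab(v), character(1))
}
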