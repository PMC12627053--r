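#' Match score between an AU coding and an emotion prototype
#'
#' The score is template coverage minus an off-template penalty:
#' `s = |A n P| / |P| - beta * |A \ P| / max(|A|, 1)` where `P` is the
#' prototype AU set for `emotion` and `A` the set of AUs active at or above
#' `tau_active`. It is 1 exactly when all and only the prototype AUs are
#' active, and bounded below by `-beta`.
#'
#' @param v Named numeric vector of AU intensities (names are AU ids).
#' @param emotion One of the six basic emotions (not neutral).
#' @param table A [prototype_table()].
#' @return Match score in `[-beta, 1]`.
#' @export
#' @examples
#' score_match(c("6" = 2, "12" = 3), "happiness", default_prototypes())
score_match <- function(v, emotion, table = default_prototypes()) {
  if (!emotion %in% BASIC_EMOTIONS) {
    stop("unknown or non-scorable emotion: ", emotion, call. = FALSE)
  }
  P <- table$prototypes[[emotion]]
  ids <- as.integer(names(v))
  if (anyNA(ids)) stop("`v` must be named by integer AU ids", call. = FALSE)
  A <- ids[v >= table$tau_active]
  length(intersect(A, P)) / length(P) -
    table$beta * length(setdiff(A, P)) / max(length(A), 1)
}

# Vectorised scorer: M is a trials x AU matrix with AU-id column names.
# Returns list(scores = trials x 6 matrix, n_active, any_expressive).
score_emotion_matrix <- function(M, table) {
  ids <- as.integer(colnames(M))
  A <- M >= table$tau_active
  nA <- rowSums(A)
  expressive <- if (any(ids != 45)) rowSums(A[, ids != 45, drop = FALSE]) > 0 else
    rep(FALSE, nrow(M))
  scores <- matrix(NA_real_, nrow(M), length(BASIC_EMOTIONS),
                   dimnames = list(NULL, BASIC_EMOTIONS))
  for (e in BASIC_EMOTIONS) {
    P <- table$prototypes[[e]]
    inP <- ids %in% P
    hit <- if (any(inP)) rowSums(A[, inP, drop = FALSE]) else rep(0, nrow(M))
    scores[, e] <- hit / length(P) - table$beta * (nA - hit) / pmax(nA, 1)
  }
  list(scores = scores, n_active = nA, any_expressive = expressive)
}

# Vectorised classifier over a trials x AU intensity matrix.
classify_expression_matrix <- function(M, table = default_prototypes()) {
  sc <- score_emotion_matrix(M, table)
  scores <- sc$scores
  best <- apply(scores, 1, max)
  out <- rep("neutral", nrow(M))
  decided <- sc$any_expressive & best >= table$s_min
  if (any(decided)) {
    idx <- which(decided)
    ids <- as.integer(colnames(M))
    for (i in idx) {
      tied <- BASIC_EMOTIONS[scores[i, ] >= best[i] - 1e-12]
      if (length(tied) > 1) {
        # tie-break: higher mean intensity over the tied prototypes' AUs,
        # then fixed emotion order
        mi <- vapply(tied, function(e) {
          P <- table$prototypes[[e]]
          mean(M[i, match(intersect(P, ids), ids)])
        }, numeric(1))
        tied <- tied[mi >= max(mi) - 1e-12]
      }
      out[i] <- tied[1]
    }
  }
  factor(out, levels = EMOTIONS)
}

#' Classify an AU coding against the emotion prototypes
#'
#' Returns `neutral` when no AU other than AU45 (blink) reaches the
#' activation threshold, or when the best prototype match score falls below
#' `s_min`; otherwise the emotion with the highest [score_match()]. Ties are
#' broken by the higher mean intensity over the tied prototypes' AUs, then
#' by the fixed order happiness, sadness, fear, anger, surprise, disgust.
#'
#' @inheritParams score_match
#' @return A length-1 factor with the seven emotion levels.
#' @export
#' @examples
#' classify_expression(c("6" = 4, "12" = 3, "25" = 2))
classify_expression <- function(v, table = default_prototypes()) {
  ids <- names(v)
  if (is.null(ids) && length(v)) stop("`v` must be named by AU id", call. = FALSE)
  M <- matrix(as.numeric(v), nrow = 1, dimnames = list(NULL, ids))
  if (!length(v)) M <- matrix(numeric(), nrow = 1, ncol = 0)
  classify_expression_matrix(M, table)[1]
}

#' Expression intensity indices over the coded emotion's prototype AUs
#'
#' Three summaries of how strongly an expression was produced, computed over
#' the prototype AU set of the coded emotion: the mean of all relevant AUs,
#' the mean of only the active (non-zero) AUs, and the maximum AU intensity.
#' For neutral the indices are computed over the full AU id set of the
#' coding.
#'
#' @inheritParams score_match
#' @param emotion The coded emotion (may be `"neutral"`).
#' @return A one-row tibble with `mean_all`, `mean_active`, `max_au`.
#' @export
#' @examples
#' intensity_indices(c("6" = 2, "12" = 4, "25" = 0), "happiness")
intensity_indices <- function(v, emotion, table = default_prototypes()) {
  if (!emotion %in% EMOTIONS) stop("unknown emotion: ", emotion, call. = FALSE)
  ids <- as.integer(names(v))
  if (emotion == "neutral") {
    vals <- as.numeric(v)
  } else {
    P <- table$prototypes[[emotion]]
    if (!length(P)) stop("empty prototype for emotion: ", emotion, call. = FALSE)
    vals <- as.numeric(v)[match(P, ids)]
    vals[is.na(vals)] <- 0  # prototype AUs absent from the coding count as 0
  }
  active <- vals > 0
  tibble::tibble(
    mean_all = mean(vals),
    mean_active = if (any(active)) mean(vals[active]) else 0,
    max_au = if (length(vals)) max(vals) else 0
  )
}

#' Keep only trials where the coded emotion matched the intended one
#'
#' Mirrors the study's retention rule: downstream agreement and intensity
#' analyses use only trials in which the human coder's emotion label equals
#' the emotion the participant was instructed to pose. The number of removed
#' trials is reported via a message and the `"n_removed"` attribute.
#'
#' @param trials Data frame with a logical `accurate` column.
#' @return The retained rows, order preserved.
#' @export
retain_accurate <- function(trials) {
  stopifnot(is.data.frame(trials), "accurate" %in% names(trials))
  keep <- trials$accurate
  out <- trials[keep, , drop = FALSE]
  n_removed <- sum(!keep)
  message(n_removed, " trial(s) removed by the retention rule")
  attr(out, "n_removed") <- n_removed
  out
}

#' Expression accuracy by blood-pressure group and emotion
#'
#' Percentage of participants in each BP group whose coded expression
#' matched the intended emotion, one cell per group x emotion (each
#' participant contributes at most one trial per emotion). Cells for groups
#' with no participants are `NA`.
#'
#' @param trials Data frame with `participant_id`, `intended`, `accurate`.
#' @param groups Data frame with `participant_id`, `bp_group`.
#' @return Tibble with `bp_group`, `emotion`, `n`, `accuracy_pct`.
#' @export
group_accuracy <- function(trials, groups) {
  dat <- dplyr::inner_join(
    dplyr::as_tibble(trials[c("participant_id", "intended", "accurate")]),
    dplyr::as_tibble(groups[c("participant_id", "bp_group")]),
    by = "participant_id"
  )
  if (anyDuplicated(dat[c("participant_id", "intended")])) {
    stop("each participant may contribute at most one trial per emotion",
         call. = FALSE)
  }
  grid_groups <- droplevels(unique(groups$bp_group))
  dat$bp_group <- factor(dat$bp_group, levels = levels(grid_groups))
  dat |>
    dplyr::group_by(bp_group = .data$bp_group, emotion = .data$intended) |>
    dplyr::summarise(
      n = dplyr::n(),
      accuracy_pct = 100 * mean(.data$accurate),
      .groups = "drop"
    ) |>
    tidyr::complete(
      bp_group = grid_groups,
      emotion = factor(EMOTIONS, levels = EMOTIONS),
      fill = list(n = 0L, accuracy_pct = NA_real_)
    ) |>
    dplyr::arrange(.data$bp_group, .data$emotion)
}
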