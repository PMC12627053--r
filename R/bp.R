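BP_GROUPS <- c("normotensive", "prehypertensive", "hypertensive_stage1", "out_of_range")

#' JNC-7 blood-pressure category from mean SBP/DBP
#'
#' Normotensive: SBP < 120 and DBP < 80. Prehypertensive: SBP 120-139 and/or
#' DBP 80-89. Stage-1 hypertensive: SBP 140-159 and/or DBP 90-99. Readings
#' at stage-2 levels (SBP >= 160 or DBP >= 100) fall outside the study's
#' recruitment range and are flagged `out_of_range`. The higher category
#' always dominates, so the mapping is monotone in both pressures.
#'
#' @param sbp,dbp Numeric vectors, mmHg.
#' @return Factor with levels normotensive, prehypertensive,
#'   hypertensive_stage1, out_of_range.
#' @export
#' @examples
#' classify_jnc7(c(119, 120, 135), c(79, 79, 92))
classify_jnc7 <- function(sbp, dbp) {
  stopifnot(length(sbp) == length(dbp))
  if (any(sbp < 50 | sbp > 260 | dbp < 30 | dbp > 150, na.rm = TRUE)) {
    stop("blood pressures outside the physiologic range", call. = FALSE)
  }
  if (any(dbp >= sbp, na.rm = TRUE)) {
    stop("diastolic pressure must be below systolic pressure", call. = FALSE)
  }
  out <- dplyr::case_when(
    sbp < 120 & dbp < 80 ~ "normotensive",
    sbp >= 160 | dbp >= 100 ~ "out_of_range",
    sbp >= 140 | dbp >= 90 ~ "hypertensive_stage1",
    TRUE ~ "prehypertensive"
  )
  factor(out, levels = BP_GROUPS)
}

#' Average repeated BP readings with the first-reading discard rule
#'
#' Automated monitors typically read high on the first cuff inflation, so the
#' first reading of each day is discarded and the remaining readings (six,
#' under the default 4-per-day/2-day protocol) are averaged arithmetically.
#'
#' @param readings Data frame with columns `day`, `index_within_day`, `sbp`,
#'   `dbp`.
#' @param readings_per_day Expected readings on each day (default 4).
#' @param days Expected number of days (default 2).
#' @return A one-row tibble with `mean_sbp` and `mean_dbp`.
#' @export
#' @examples
#' r <- tibble::tibble(
#'   day = rep(1:2, each = 4), index_within_day = rep(1:4, 2),
#'   sbp = c(130, 120, 118, 119, 125, 117, 118, 120),
#'   dbp = c(85, 80, 79, 80, 82, 78, 79, 80)
#' )
#' average_readings(r)
average_readings <- function(readings, readings_per_day = 4, days = 2) {
  stopifnot(all(c("day", "index_within_day", "sbp", "dbp") %in% names(readings)))
  for (d in seq_len(days)) {
    n_d <- sum(readings$day == d)
    if (n_d != readings_per_day) {
      stop(sprintf("day %d has %d reading(s); expected %d", d, n_d,
                   readings_per_day), call. = FALSE)
    }
  }
  kept <- readings[readings$index_within_day != 1, , drop = FALSE]
  tibble::tibble(mean_sbp = mean(kept$sbp), mean_dbp = mean(kept$dbp))
}

#' Blood-pressure profiles for a participants table
#'
#' Applies the first-reading discard rule to the wide reading columns
#' (`d1_sbp1..d1_sbp4`, `d2_sbp1..`, and the `dbp` analogues), averages the
#' remaining six readings, and attaches the JNC-7 category.
#'
#' @param participants Participants data frame in the wide reading layout.
#' @return The input as a tibble with `mean_sbp`, `mean_dbp`, `bp_group`
#'   columns appended.
#' @export
bp_profiles <- function(participants) {
  need <- c(paste0("d1_sbp", 1:4), paste0("d1_dbp", 1:4),
            paste0("d2_sbp", 1:4), paste0("d2_dbp", 1:4))
  missing <- setdiff(need, names(participants))
  if (length(missing)) {
    stop("participants table lacks reading column(s): ", toString(missing),
         call. = FALSE)
  }
  sbp_cols <- c(paste0("d1_sbp", 2:4), paste0("d2_sbp", 2:4))
  dbp_cols <- c(paste0("d1_dbp", 2:4), paste0("d2_dbp", 2:4))
  out <- dplyr::as_tibble(participants)
  out$mean_sbp <- rowMeans(out[sbp_cols])
  out$mean_dbp <- rowMeans(out[dbp_cols])
  out$bp_group <- classify_jnc7(out$mean_sbp, out$mean_dbp)
  out
}
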