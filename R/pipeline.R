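#' Assemble paired expression trials from the two coders' payloads
#'
#' Joins the human coding table with the automated coder's rows by
#' participant and emotion, producing one trial per human-coded image with
#' list-column AU vectors for both raters. Rows already excluded from the
#' machine payload (detector failure) leave the machine vector `NULL`.
#'
#' @param human Human coding tibble (see [read_human_csv()]).
#' @param machine Automated coding tibble (see [read_openface_csv()]), or
#'   `NULL`.
#' @param prototypes Prototype table (for accuracy labelling).
#' @return Tibble with `participant_id`, `intended`, `coded`, `accurate`,
#'   and list-columns `human`, `machine`. Audit counts are attached as
#'   attributes `n_images`, `n_missing_machine`.
#' @export
assemble_trials <- function(human, machine = NULL, prototypes = default_prototypes()) {
  au_cols <- sprintf("AU%02d", human_au_ids())
  Mh <- as.matrix(human[au_cols])
  colnames(Mh) <- as.character(human_au_ids())
  trials <- tibble::tibble(
    participant_id = human$participant_id,
    intended = factor(human$emotion_intended, levels = EMOTIONS),
    coded = factor(human$emotion_coded, levels = EMOTIONS),
    accurate = human$emotion_intended == human$emotion_coded,
    human = purrr::map(seq_len(nrow(Mh)), function(i) Mh[i, ])
  )
  trials$machine <- vector("list", nrow(trials))
  n_missing <- nrow(trials)
  if (!is.null(machine)) {
    m_au_cols <- grep("^AU[0-9]{2}_r$", names(machine), value = TRUE)
    m_ids <- as.integer(sub("^AU([0-9]{2})_r$", "\\1", m_au_cols))
    Mm <- as.matrix(machine[m_au_cols])
    colnames(Mm) <- as.character(m_ids)
    key <- paste(machine$participant_id, machine$emotion, sep = "\r")
    hit <- match(paste(trials$participant_id, as.character(trials$intended), sep = "\r"), key)
    found <- which(!is.na(hit))
    trials$machine[found] <- purrr::map(hit[found], function(i) Mm[i, ])
    n_missing <- nrow(trials) - length(found)
  }
  attr(trials, "n_images") <- nrow(trials)
  attr(trials, "n_missing_machine") <- n_missing
  trials
}

demographics_table <- function(profiles) {
  by_group <- profiles |>
    dplyr::group_by(bp_group = .data$bp_group) |>
    dplyr::summarise(
      n = dplyr::n(),
      age_mean = mean(.data$age), age_sd = sd(.data$age),
      n_male = sum(.data$gender == "male"),
      n_female = sum(.data$gender == "female"),
      education_mean = mean(.data$education_years),
      education_sd = sd(.data$education_years),
      sbp_mean = mean(.data$mean_sbp), sbp_sd = sd(.data$mean_sbp),
      dbp_mean = mean(.data$mean_dbp), dbp_sd = sd(.data$mean_dbp),
      .groups = "drop"
    )
  test_of <- function(prefix) {
    s <- by_group[c("n", paste0(prefix, "_mean"), paste0(prefix, "_sd"))]
    names(s) <- c("n", "mean", "sd")
    res <- anova_from_summaries(s)
    tibble::tibble(variable = prefix, statistic = res$statistic,
                   df1 = res$df1, df2 = res$df2, p_value = res$p_value)
  }
  tests <- dplyr::bind_rows(lapply(c("age", "education", "sbp", "dbp"), test_of))
  gender_tab <- as.matrix(by_group[c("n_male", "n_female")])
  rownames(gender_tab) <- as.character(by_group$bp_group)
  chi <- chi_square_independence(gender_tab)
  tests <- dplyr::bind_rows(
    tests,
    tibble::tibble(variable = "gender", statistic = chi$statistic,
                   df1 = chi$df, df2 = NA_real_, p_value = chi$p_value)
  )
  list(summary = by_group, tests = tests)
}

star_of <- function(p) {
  dplyr::case_when(is.na(p) ~ "", p < .001 ~ "***", p < .01 ~ "**",
                   p < .05 ~ "*", TRUE ~ "")
}

#' Run the full expression-dampening analysis pipeline
#'
#' Chains every stage of the analysis: JNC-7 BP classification;
#' per-emotion expression accuracy by group with ANCOVA (controlling for
#' age, gender and education), partial eta squared and Bonferroni subset
#' letters; the retention filter (only trials whose coded label matches the
#' intended emotion continue); the three intensity indices for both raters;
#' five-index human-machine agreement panels aggregated by group; partial
#' correlations of SBP and DBP with per-emotion accuracy; and an audit log
#' of every record's fate.
#'
#' @param participants Participants tibble or path to the participants CSV.
#' @param human Human coding tibble or path.
#' @param machine Automated coding tibble or path (optional; agreement and
#'   machine intensity stages are skipped without it).
#' @param prototypes Prototype table.
#' @param icc_variant ICC(3,1) variant for the agreement panels.
#' @param alpha Significance level for subset letters.
#' @param out_dir If given, tidy CSV outputs and a JSON run log are written
#'   there.
#' @return Object of class `facedamp_run`: list with `demographics`,
#'   `accuracy`, `agreement`, `intensity`, `correlations`, `log`.
#' @export
#' @examples
#' \donttest{
#' study <- generate_study(synth_config(group_sizes = c(
#'   normotensive = 8, prehypertensive = 6, hypertensive_stage1 = 6)))
#' run <- run_pipeline(study$participants, study$human, study$machine)
#' run$accuracy$table
#' }
run_pipeline <- function(participants, human, machine = NULL,
                         prototypes = default_prototypes(),
                         icc_variant = c("consistency", "absolute"),
                         alpha = 0.05, out_dir = NULL) {
  icc_variant <- match.arg(icc_variant)
  stage <- "input"
  log <- list()
  result <- tryCatch({
    if (is.character(participants)) participants <- read_participants_csv(participants)
    if (is.character(human)) human <- read_human_csv(human, prototypes)
    n_excluded_success <- 0L
    if (is.character(machine)) {
      machine <- read_openface_csv(machine)
      n_excluded_success <- attr(machine, "n_excluded_success") %||% 0L
    } else if (!is.null(machine) && "success" %in% names(machine)) {
      n_excluded_success <- sum(machine$success == 0)
      machine <- machine[machine$success != 0, , drop = FALSE]
    }
    log$n_label_fallback <- attr(human, "n_label_fallback") %||% 0L

    stage <- "bp_classification"
    profiles <- bp_profiles(participants)
    demographics <- demographics_table(profiles)
    groups <- profiles[c("participant_id", "bp_group")]

    stage <- "trial_assembly"
    trials <- assemble_trials(human, machine, prototypes)
    log$n_images <- attr(trials, "n_images")
    log$n_machine_rows_excluded_success <- n_excluded_success
    log$n_missing_machine <- attr(trials, "n_missing_machine")

    stage <- "accuracy"
    acc_tbl <- group_accuracy(trials, groups)
    acc_dat <- dplyr::inner_join(
      tibble::tibble(participant_id = trials$participant_id,
                     emotion = as.character(trials$intended),
                     accuracy = 100 * as.numeric(trials$accurate)),
      profiles[c("participant_id", "age", "gender", "education_years", "bp_group")],
      by = "participant_id"
    )
    anc_rows <- purrr::map(EMOTIONS, function(e) {
      d <- acc_dat[acc_dat$emotion == e, ]
      if (!nrow(d) || dplyr::n_distinct(d$bp_group) < 2) {
        return(tibble::tibble(emotion = e, statistic = NA_real_, df1 = NA_real_,
                              df2 = NA_real_, p_value = NA_real_,
                              partial_eta2 = NA_real_, letters = NA_character_))
      }
      fit <- fit_ancova(d, "accuracy", "bp_group",
                        c("age", "gender", "education_years"))
      lets <- if (is.na(fit$statistic)) NA_character_ else
        paste(bonferroni_subsets(fit, alpha)$letters$letters, collapse = "/")
      gl <- glance(fit)
      tibble::tibble(emotion = e, statistic = gl$statistic, df1 = gl$df1,
                     df2 = gl$df2, p_value = gl$p_value,
                     partial_eta2 = gl$partial_eta2, letters = lets)
    })
    anc_tbl <- dplyr::bind_rows(anc_rows)
    anc_tbl$significance <- star_of(anc_tbl$p_value)
    accuracy <- list(
      table = acc_tbl |>
        tidyr::pivot_wider(id_cols = "emotion", names_from = "bp_group",
                           values_from = "accuracy_pct") |>
        dplyr::left_join(anc_tbl, by = "emotion"),
      by_cell = acc_tbl, ancova = anc_tbl
    )
    log$n_undefined_ancova <- sum(is.na(anc_tbl$statistic))

    stage <- "retention"
    retained <- suppressMessages(retain_accurate(trials))
    log$n_retention_removed <- attr(retained, "n_removed")
    log$n_analyzed <- nrow(retained)

    stage <- "intensity"
    intensity <- intensity_summary(retained, groups, profiles, prototypes)

    stage <- "agreement"
    agreement <- NULL
    if (!is.null(machine)) {
      panels <- trial_panels(retained, icc_variant = icc_variant)
      agreement <- group_mean_panel(panels, groups)
      log$n_undefined_panels <- list(
        kappa = sum(is.na(panels$kappa) & !purrr::map_lgl(panels$machine, is.null)),
        alpha = sum(is.na(panels$alpha) & !purrr::map_lgl(panels$machine, is.null)),
        icc = sum(is.na(panels$icc) & !purrr::map_lgl(panels$machine, is.null))
      )
    }

    stage <- "partial_correlations"
    correlations <- purrr::map(EMOTIONS, function(e) {
      d <- acc_dat[acc_dat$emotion == e, ]
      d <- dplyr::inner_join(d, profiles[c("participant_id", "mean_sbp", "mean_dbp")],
                             by = "participant_id")
      covs <- d[c("age", "gender", "education_years")]
      rbind(
        cbind(bp = "sbp", emotion = e,
              partial_correlation(d$mean_sbp, d$accuracy, covs)),
        cbind(bp = "dbp", emotion = e,
              partial_correlation(d$mean_dbp, d$accuracy, covs))
      )
    }) |> dplyr::bind_rows() |> dplyr::as_tibble()
    correlations$significance <- star_of(correlations$p_value)

    stage <- "audit"
    if (log$n_images != log$n_analyzed + log$n_retention_removed) {
      stop("audit failure: analyzed + removed != input images")
    }
    log$accounting <- sprintf(
      "%d images = %d analyzed + %d retention-removed; machine: %d success-excluded, %d unmatched",
      log$n_images, log$n_analyzed, log$n_retention_removed,
      log$n_machine_rows_excluded_success, log$n_missing_machine)

    structure(
      list(demographics = demographics, accuracy = accuracy,
           agreement = agreement, intensity = intensity,
           correlations = correlations, log = log),
      class = "facedamp_run"
    )
  }, error = function(e) {
    stop(sprintf("pipeline stage `%s` failed: %s", stage, conditionMessage(e)),
         call. = FALSE)
  })

  if (!is.null(out_dir)) write_run(result, out_dir)
  result
}

intensity_summary <- function(retained, groups, profiles, prototypes) {
  if (!nrow(retained)) {
    return(tibble::tibble())
  }
  per_trial <- purrr::pmap(
    list(retained$human, retained$machine, as.character(retained$coded)),
    function(h, m, emo) {
      hi <- intensity_indices(h, emo, prototypes)
      names(hi) <- paste0("human_", names(hi))
      if (is.null(m)) {
        mi <- tibble::tibble(machine_mean_all = NA_real_,
                             machine_mean_active = NA_real_,
                             machine_max_au = NA_real_)
      } else {
        mi <- intensity_indices(m, emo, prototypes)
        names(mi) <- paste0("machine_", names(mi))
      }
      dplyr::bind_cols(hi, mi)
    }
  ) |> dplyr::bind_rows()
  dat <- dplyr::bind_cols(
    retained[c("participant_id", "intended")], per_trial
  ) |>
    dplyr::inner_join(
      profiles[c("participant_id", "bp_group", "age", "gender", "education_years")],
      by = "participant_id"
    )
  idx <- grep("^(human|machine)_", names(per_trial), value = TRUE)
  summary <- dat |>
    dplyr::group_by(bp_group = .data$bp_group, emotion = .data$intended) |>
    dplyr::summarise(
      n = dplyr::n(),
      dplyr::across(dplyr::all_of(idx),
                    list(mean = ~ mean(.x, na.rm = TRUE), sd = ~ sd(.x, na.rm = TRUE))),
      .groups = "drop"
    )
  # ANCOVA on the headline index (mean of active AUs) per emotion and rater
  anc <- purrr::map(unique(as.character(dat$intended)), function(e) {
    d <- dat[as.character(dat$intended) == e, ]
    f_of <- function(col) {
      d2 <- d[!is.na(d[[col]]), ]
      if (nrow(d2) < 8 || dplyr::n_distinct(d2$bp_group) < 2) return(NA_real_)
      fit <- tryCatch(fit_ancova(d2, col, "bp_group",
                                 c("age", "gender", "education_years")),
                      error = function(e) NULL)
      if (is.null(fit)) NA_real_ else fit$statistic
    }
    tibble::tibble(emotion = e,
                   human_F = f_of("human_mean_active"),
                   machine_F = f_of("machine_mean_active"))
  }) |> dplyr::bind_rows()
  list(summary = summary, ancova = anc)
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(run$demographics$summary,
                   file.path(out_dir, "table1_demographics.csv"))
  readr::write_csv(run$demographics$tests,
                   file.path(out_dir, "table1_tests.csv"))
  readr::write_csv(run$accuracy$table, file.path(out_dir, "table2_accuracy.csv"))
  if (!is.null(run$agreement)) {
    readr::write_csv(run$agreement, file.path(out_dir, "table3_agreement.csv"))
  }
  if (length(run$intensity)) {
    readr::write_csv(run$intensity$summary,
                     file.path(out_dir, "table3_intensity.csv"))
  }
  readr::write_csv(run$correlations,
                   file.path(out_dir, "table4_partial_correlations.csv"))
  jsonlite::write_json(run$log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.facedamp_run <- function(x, ...) {
  cat("<facedamp pipeline run>\n")
  cat(" ", x$log$accounting, "\n")
  cat("  tables: demographics, accuracy, agreement, intensity, correlations\n")
  invisible(x)
}
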