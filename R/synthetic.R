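#' Configuration for a synthetic expression-dampening study
#'
#' Fully parameterises the generative model used for end-to-end testing and
#' parameter-recovery simulations: JNC-7 group sizes and blood-pressure
#' sampling windows, demographic distributions, a logistic accuracy model in
#' systolic BP, an intensity model with per-group dampening, sparse
#' off-prototype AU activation, and a machine rater that is a noisy,
#' attenuated, dropout-prone transform of the human coding.
#'
#' The accuracy model sets the probability that a participant produces the
#' intended prototype to `plogis(beta0_e - beta1_e * (SBP - 100) / 10)`
#' (logit units per 10 mmHg of systolic pressure). On the correct path,
#' prototype AU intensities are `clamp(round(N(mu_e - dampening * g,
#' sigma)), 1, 5)` with `g` the group index 0/1/2; on the incorrect path the
#' participant produces either a sub-threshold partial prototype or the full
#' prototype of a confusable emotion, with equal probability. Noise AUs are
#' drawn only from AUs belonging to no emotion prototype, so correct
#' productions always classify as the intended emotion.
#'
#' @param group_sizes Named counts for the three JNC-7 groups.
#' @param seed Integer seed used by [generate_study()].
#' @param bp_windows Per-group uniform sampling windows (mmHg) for the
#'   latent target SBP/DBP; each window must classify inside its group.
#' @param reading_noise_sd SD (mmHg) of per-reading measurement noise.
#' @param first_reading_bump Elevation (mmHg) of each day's first reading,
#'   so the discard rule is exercised.
#' @param age_mean,age_sd,p_male Per-group demographic parameters.
#' @param education_mean,education_sd Education (years), common to groups.
#' @param beta0,beta1 Named per-emotion accuracy-model coefficients (logit
#'   scale; `beta1` in logit per 10 mmHg SBP).
#' @param mu Named per-emotion base intensity means (intensity units).
#' @param dampening Intensity reduction per group step (intensity units).
#' @param sigma Intensity SD (intensity units).
#' @param p_noise Per-AU activation probability for off-prototype noise AUs.
#' @param noise_intensity Intensities sampled for active noise AUs.
#' @param gain Machine multiplicative attenuation of the human intensity.
#' @param machine_noise_sd SD of the machine's additive noise.
#' @param dropout Machine per-AU miss scale: an AU with human intensity `h`
#'   is missed (output 0) with probability `dropout * exp(-h)`.
#' @param p_fail Probability that the machine fails on an image entirely
#'   (row emitted with `success = 0`).
#' @param prototypes Prototype table used for coding labels.
#' @return An object of class `facedamp_config`.
#' @export
synth_config <- function(
    group_sizes = c(normotensive = 33, prehypertensive = 21, hypertensive_stage1 = 20),
    seed = 1L,
    bp_windows = list(
      normotensive        = list(sbp = c(96, 117), dbp = c(62, 77)),
      prehypertensive     = list(sbp = c(122, 137), dbp = c(80, 87)),
      hypertensive_stage1 = list(sbp = c(141, 157), dbp = c(90, 97))
    ),
    reading_noise_sd = 1.5,
    first_reading_bump = 6,
    age_mean = c(normotensive = 24.4, prehypertensive = 30.1, hypertensive_stage1 = 40.3),
    age_sd = c(normotensive = 6.7, prehypertensive = 9.9, hypertensive_stage1 = 13.5),
    p_male = c(normotensive = 0.33, prehypertensive = 0.76, hypertensive_stage1 = 0.65),
    education_mean = 16.2, education_sd = 2.2,
    beta0 = c(happiness = 3.2, sadness = 2.8, fear = 0.5, anger = 1.1,
              surprise = 2.3, disgust = 0.7),
    beta1 = c(happiness = 0, sadness = 0.9, fear = 0.75, anger = 0.35,
              surprise = 0.85, disgust = 0.15),
    mu = c(happiness = 2.2, sadness = 1.7, fear = 1.6, anger = 1.8,
           surprise = 2.2, disgust = 2.0),
    dampening = 0.25, sigma = 0.8,
    p_noise = 0.05, noise_intensity = 1:2,
    gain = 0.75, machine_noise_sd = 0.35, dropout = 0.5, p_fail = 0.02,
    prototypes = default_prototypes()) {
  grp <- names(BP_GROUP_SIZES_CHECK(group_sizes))
  probs <- c(p_male, p_noise, dropout, p_fail)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(mu < 0 | mu > 5)) stop("base intensity means must lie in [0, 5]", call. = FALSE)
  for (g in grp) {
    w <- bp_windows[[g]]
    corners <- expand.grid(sbp = w$sbp, dbp = w$dbp)
    if (!all(classify_jnc7(corners$sbp, corners$dbp) == g)) {
      stop("bp window for ", g, " leaves its JNC-7 category", call. = FALSE)
    }
  }
  if (!setequal(names(beta0), BASIC_EMOTIONS) || !setequal(names(beta1), BASIC_EMOTIONS) ||
      !setequal(names(mu), BASIC_EMOTIONS)) {
    stop("beta0, beta1 and mu must be named by the six basic emotions", call. = FALSE)
  }
  structure(
    list(group_sizes = group_sizes, seed = as.integer(seed),
         bp_windows = bp_windows, reading_noise_sd = reading_noise_sd,
         first_reading_bump = first_reading_bump,
         age_mean = age_mean, age_sd = age_sd, p_male = p_male,
         education_mean = education_mean, education_sd = education_sd,
         beta0 = beta0[BASIC_EMOTIONS], beta1 = beta1[BASIC_EMOTIONS],
         mu = mu[BASIC_EMOTIONS], dampening = dampening, sigma = sigma,
         p_noise = p_noise, noise_intensity = noise_intensity,
         gain = gain, machine_noise_sd = machine_noise_sd,
         dropout = dropout, p_fail = p_fail, prototypes = prototypes),
    class = "facedamp_config"
  )
}

BP_GROUP_SIZES_CHECK <- function(group_sizes) {
  if (!setequal(names(group_sizes), BP_GROUPS[1:3])) {
    stop("group_sizes must be named normotensive / prehypertensive / hypertensive_stage1",
         call. = FALSE)
  }
  if (any(group_sizes < 1)) stop("group sizes must be at least 1", call. = FALSE)
  group_sizes[BP_GROUPS[1:3]]
}

# AUs belonging to no prototype (and not the blink AU): safe carriers of
# off-template noise.
noise_au_pool <- function(prototypes, au_ids = human_au_ids()) {
  used <- unique(unlist(prototypes$prototypes))
  setdiff(au_ids, c(used, 45L))
}

#' Generate synthetic participants with repeated BP readings
#'
#' Draws a latent target pressure uniformly inside each group's window,
#' emits 4 integer readings per day over 2 days with measurement noise and
#' an elevated first reading per day, and resamples until the
#' discard-rule mean classifies into the intended group (immediate with
#' zero reading noise).
#'
#' @param cfg A [synth_config()].
#' @return Tibble in the wide participants layout (`participant_id`, `age`,
#'   `gender`, `education_years`, `d1_sbp1..4`, `d1_dbp1..4`, `d2_sbp1..4`,
#'   `d2_dbp1..4`) plus a `true_group` column recording the sampled group.
#' @export
generate_participants <- function(cfg) {
  sizes <- BP_GROUP_SIZES_CHECK(cfg$group_sizes)
  groups <- rep(names(sizes), times = sizes)
  n <- length(groups)
  w_sbp <- t(vapply(groups, function(g) cfg$bp_windows[[g]]$sbp, numeric(2)))
  w_dbp <- t(vapply(groups, function(g) cfg$bp_windows[[g]]$dbp, numeric(2)))

  draw_readings <- function(target) {
    # 8 readings (4 x 2 days), integers, first of each day elevated
    r <- matrix(rnorm(n * 8, mean = target, sd = cfg$reading_noise_sd), n, 8)
    r[, c(1, 5)] <- r[, c(1, 5)] + cfg$first_reading_bump
    round(r)
  }

  sbp_t <- runif(n, w_sbp[, 1], w_sbp[, 2])
  dbp_t <- runif(n, w_dbp[, 1], w_dbp[, 2])
  sbp_r <- draw_readings(sbp_t)
  dbp_r <- draw_readings(dbp_t)
  for (iter in 1:50) {
    m_sbp <- rowMeans(sbp_r[, c(2:4, 6:8), drop = FALSE])
    m_dbp <- rowMeans(dbp_r[, c(2:4, 6:8), drop = FALSE])
    bad <- which(as.character(classify_jnc7(m_sbp, m_dbp)) != groups)
    if (!length(bad)) break
    redo_s <- matrix(rnorm(length(bad) * 8, mean = sbp_t[bad], sd = cfg$reading_noise_sd),
                     length(bad), 8)
    redo_d <- matrix(rnorm(length(bad) * 8, mean = dbp_t[bad], sd = cfg$reading_noise_sd),
                     length(bad), 8)
    redo_s[, c(1, 5)] <- redo_s[, c(1, 5)] + cfg$first_reading_bump
    redo_d[, c(1, 5)] <- redo_d[, c(1, 5)] + cfg$first_reading_bump
    sbp_r[bad, ] <- round(redo_s)
    dbp_r[bad, ] <- round(redo_d)
  }

  age <- pmin(65, pmax(18, round(rnorm(n, cfg$age_mean[groups], cfg$age_sd[groups]))))
  gender <- ifelse(rbinom(n, 1, cfg$p_male[groups]) == 1, "male", "female")
  edu <- pmin(22, pmax(8, round(rnorm(n, cfg$education_mean, cfg$education_sd))))

  out <- tibble::tibble(
    participant_id = sprintf("P%03d", seq_len(n)),
    age = as.numeric(age), gender = gender, education_years = as.numeric(edu)
  )
  cols <- as.data.frame(cbind(sbp_r[, 1:4], dbp_r[, 1:4], sbp_r[, 5:8], dbp_r[, 5:8]))
  names(cols) <- c(paste0("d1_sbp", 1:4), paste0("d1_dbp", 1:4),
                   paste0("d2_sbp", 1:4), paste0("d2_dbp", 1:4))
  out <- dplyr::bind_cols(out, dplyr::as_tibble(cols))
  out$true_group <- groups
  out
}

#' Generate human FACS codings for the study's posed expressions
#'
#' One coding per participant x emotion. Correctness is drawn from the
#' logistic accuracy model in mean systolic BP; the coded label is produced
#' by running the prototype classifier on the generated AU vector, which on
#' the correct path always recovers the intended emotion. Neutral poses are
#' near-zero vectors with sparse noise only.
#'
#' @param participants Output of [generate_participants()].
#' @param cfg A [synth_config()].
#' @param emotions Emotions to generate (default all seven).
#' @return List with `human` (wide coding tibble: `participant_id`,
#'   `emotion_intended`, `emotion_coded`, `AU01..AU45`) and `truth`
#'   (tibble with the latent correctness draw per trial).
#' @export
generate_expressions <- function(participants, cfg, emotions = EMOTIONS) {
  stopifnot(all(emotions %in% EMOTIONS))
  prof <- bp_profiles(participants)
  n <- nrow(prof)
  g_idx <- match(prof$true_group %||% as.character(prof$bp_group), BP_GROUPS) - 1L
  au_ids <- human_au_ids()
  pool <- noise_au_pool(cfg$prototypes, au_ids)
  clamp15 <- function(x) pmin(5, pmax(1, round(x)))

  human_rows <- list(); truth_rows <- list()
  for (e in emotions) {
    M <- matrix(0, n, length(au_ids), dimnames = list(NULL, as.character(au_ids)))
    if (e == "neutral") {
      correct <- rep(NA, n)
      p_corr <- rep(NA_real_, n)
    } else {
      P <- cfg$prototypes$prototypes[[e]]
      mu_eff <- cfg$mu[[e]] - cfg$dampening * g_idx
      p_corr <- stats::plogis(cfg$beta0[[e]] - cfg$beta1[[e]] * (prof$mean_sbp - 100) / 10)
      correct <- rbinom(n, 1, p_corr) == 1
      ok <- which(correct)
      if (length(ok)) {
        M[ok, as.character(P)] <-
          clamp15(rnorm(length(ok) * length(P), mean = mu_eff[ok], sd = cfg$sigma))
      }
      bad <- which(!correct)
      if (length(bad)) {
        confus <- CONFUSABLE[[e]]
        P_conf <- cfg$prototypes$prototypes[[confus]]
        use_conf <- rbinom(length(bad), 1, 0.5) == 1
        conf_rows <- bad[use_conf]
        if (length(conf_rows)) {
          M[conf_rows, as.character(P_conf)] <-
            clamp15(rnorm(length(conf_rows) * length(P_conf),
                          mean = mu_eff[conf_rows], sd = cfg$sigma))
        }
        part_rows <- bad[!use_conf]
        m_e <- ceiling(length(P) / 2) - 1L  # strict subset below the s_min coverage
        if (length(part_rows) && m_e > 0) {
          for (i in part_rows) {
            sel <- sample(P, m_e)
            M[i, as.character(sel)] <- clamp15(rnorm(m_e, mu_eff[i], cfg$sigma))
          }
        }
      }
    }
    if (length(pool) && cfg$p_noise > 0) {
      hits <- matrix(rbinom(n * length(pool), 1, cfg$p_noise), n, length(pool))
      vals <- matrix(sample(cfg$noise_intensity, n * length(pool), replace = TRUE),
                     n, length(pool))
      M[, as.character(pool)] <- hits * vals
    }
    coded <- as.character(classify_expression_matrix(M, cfg$prototypes))
    human_rows[[e]] <- tibble::tibble(
      participant_id = prof$participant_id,
      emotion_intended = e, emotion_coded = coded
    ) |>
      dplyr::bind_cols(au_matrix_to_tibble(M))
    truth_rows[[e]] <- tibble::tibble(
      participant_id = prof$participant_id, emotion = e,
      p_correct = p_corr, correct = correct
    )
  }
  list(human = dplyr::bind_rows(human_rows), truth = dplyr::bind_rows(truth_rows))
}

CONFUSABLE <- c(sadness = "fear", fear = "sadness", anger = "disgust",
                disgust = "anger", surprise = "fear", happiness = "surprise")

au_matrix_to_tibble <- function(M) {
  colnames(M) <- sprintf("AU%02d", as.integer(colnames(M)))
  dplyr::as_tibble(M)
}

#' Simulate the automated coder's rating of a human-coded face
#'
#' Per AU with human intensity `h`: with probability `dropout * exp(-h)` the
#' machine misses the AU and outputs 0; otherwise it outputs
#' `clamp(gain * h + N(0, machine_noise_sd), 0, 5)`, rounded to 3 decimals.
#' Sub-threshold (low-intensity) activations are therefore both underrated
#' and frequently missed, as automated detectors tend to be.
#'
#' @param human Named AU intensity vector, or a trials x AU matrix with AU-id
#'   column names.
#' @param cfg A [synth_config()].
#' @return Object of the same shape as `human` with machine intensities.
#' @export
simulate_machine_rating <- function(human, cfg) {
  vec <- is.null(dim(human))
  M <- if (vec) matrix(as.numeric(human), 1, dimnames = list(NULL, names(human))) else human
  miss <- matrix(runif(length(M)) < cfg$dropout * exp(-M), nrow(M), ncol(M))
  val <- cfg$gain * M + matrix(rnorm(length(M), sd = cfg$machine_noise_sd),
                               nrow(M), ncol(M))
  out <- round(ifelse(miss, 0, pmin(5, pmax(0, val))), 3)
  dimnames(out) <- dimnames(M)
  if (vec) out <- setNames(as.numeric(out), colnames(out))
  out
}

#' Generate a complete synthetic study
#'
#' Participants with BP readings, human FACS codings for the seven
#' expressions, an automated-coder payload in the OpenFace column dialect,
#' and a ground-truth record of every generative parameter and latent
#' correctness draw. Deterministic given `cfg$seed`.
#'
#' @param cfg A [synth_config()].
#' @param emotions Emotions to generate (default all seven).
#' @return Object of class `facedamp_study`: list with `participants`,
#'   `human`, `machine`, `truth`.
#' @export
#' @examples
#' study <- generate_study(synth_config(group_sizes = c(
#'   normotensive = 4, prehypertensive = 3, hypertensive_stage1 = 3)))
#' nrow(study$human)
generate_study <- function(cfg = synth_config(), emotions = EMOTIONS) {
  withr::with_seed(cfg$seed, {
    participants <- generate_participants(cfg)
    expr <- generate_expressions(participants, cfg, emotions)
    human <- expr$human

    mach_ids <- openface_au_ids()
    H <- as.matrix(human[sprintf("AU%02d", mach_ids)])
    colnames(H) <- as.character(mach_ids)
    Mm <- simulate_machine_rating(H, cfg)
    machine <- tibble::tibble(
      participant_id = human$participant_id,
      emotion = human$emotion_intended,
      frame = 1,
      confidence = round(runif(nrow(human), 0.85, 0.99), 3),
      success = as.numeric(rbinom(nrow(human), 1, 1 - cfg$p_fail))
    )
    Mt <- Mm
    colnames(Mt) <- sprintf("AU%02d_r", mach_ids)
    machine <- dplyr::bind_cols(machine, dplyr::as_tibble(Mt))

    structure(
      list(participants = participants, human = human, machine = machine,
           truth = list(config = cfg, trials = expr$truth)),
      class = "facedamp_study"
    )
  })
}

#' @export
print.facedamp_study <- function(x, ...) {
  cat(sprintf("<facedamp synthetic study: %d participants, %d expression records>\n",
              nrow(x$participants), nrow(x$human)))
  invisible(x)
}

#' Write a synthetic study to CSV files plus a ground-truth sidecar
#'
#' Emits `participants.csv`, `human_coding.csv`, `openface_coding.csv` (the
#' three pipeline input formats) and `ground_truth.json` holding the full
#' generator configuration and latent correctness record.
#'
#' @param study A `facedamp_study`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "facedamp_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("participants.csv", "human_coding.csv",
                            "openface_coding.csv", "ground_truth.json"))
  readr::write_csv(study$participants, paths[1])
  readr::write_csv(study$human, paths[2])
  readr::write_csv(study$machine, paths[3])
  truth <- study$truth
  truth$config <- unclass(truth$config)
  truth$config$prototypes <- unclass(truth$config$prototypes)
  jsonlite::write_json(truth, paths[4], auto_unbox = TRUE, digits = NA, null = "null")
  invisible(paths)
}

#' Sparse-coding agreement simulation (kappa-paradox regime)
#'
#' Generates paired codings in the subthreshold regime: each of `n_units`
#' AUs is active at trace intensity with probability `p_active`, and the
#' machine is a strongly attenuating, dropout-prone transform. In this
#' regime raw percent agreement stays high (most AUs are zero for both
#' raters) while Cohen's kappa collapses and Gwet's AC1 remains high -- the
#' kappa paradox.
#'
#' @param n_trials Number of paired codings to simulate.
#' @param n_units AUs per coding (default 17, the machine intensity set).
#' @param p_active Per-AU activation probability for the human coder.
#' @param intensity Human intensity of active AUs (trace level 1).
#' @param gain,machine_noise_sd,dropout Machine transform parameters (see
#'   [synth_config()]); defaults represent a detector that underrates and
#'   misses subthreshold activations.
#' @param seed Optional seed.
#' @return Tibble with one row per trial: the five agreement indices.
#' @export
simulate_sparse_codings <- function(n_trials = 1000, n_units = 17,
                                    p_active = 0.1, intensity = 1,
                                    gain = 0.4, machine_noise_sd = 0.35,
                                    dropout = 0.9, seed = NULL) {
  run <- function() {
    cfg <- list(gain = gain, machine_noise_sd = machine_noise_sd, dropout = dropout)
    H <- matrix(rbinom(n_trials * n_units, 1, p_active) * intensity,
                n_trials, n_units,
                dimnames = list(NULL, as.character(seq_len(n_units))))
    M <- simulate_machine_rating(H, cfg)
    purrr::map(seq_len(n_trials),
               function(i) agreement_panel(H[i, ], M[i, ])) |>
      dplyr::bind_rows()
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}
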