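#' Read the participants CSV
#'
#' Expected wide layout: `participant_id, age, gender, education_years,
#' d1_sbp1..d1_sbp4, d1_dbp1..d1_dbp4, d2_sbp1..d2_sbp4, d2_dbp1..d2_dbp4`.
#'
#' @param path File path.
#' @return Tibble.
#' @export
read_participants_csv <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_read_problems(dat, path)
  need <- c("participant_id", "age", "gender", "education_years",
            paste0("d1_sbp", 1:4), paste0("d1_dbp", 1:4),
            paste0("d2_sbp", 1:4), paste0("d2_dbp", 1:4))
  missing <- setdiff(need, names(dat))
  if (length(missing)) {
    stop("participants file lacks column(s): ", toString(missing), call. = FALSE)
  }
  dat
}

#' Read the human FACS coding CSV
#'
#' Wide layout `participant_id, emotion_intended, emotion_coded,
#' AU01..AU45`, integer intensities 0-5. Out-of-range or non-integer
#' intensities raise an error naming the offending cell. Missing coded
#' labels are filled by the prototype classifier as a documented fallback
#' (the human label is the study's gold standard when present); the number
#' of fallback rows is recorded in the `"n_label_fallback"` attribute.
#'
#' @param path File path.
#' @param prototypes Prototype table for the classifier fallback.
#' @return Tibble.
#' @export
read_human_csv <- function(path, prototypes = default_prototypes()) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_read_problems(dat, path)
  au_cols <- sprintf("AU%02d", human_au_ids())
  missing <- setdiff(c("participant_id", "emotion_intended", au_cols), names(dat))
  if (length(missing)) {
    stop("human coding file lacks column(s): ", toString(missing), call. = FALSE)
  }
  for (cl in au_cols) {
    x <- dat[[cl]]
    bad <- which(is.na(x) | x < 0 | x > 5 | x != round(x))
    if (length(bad)) {
      stop(sprintf("invalid human AU intensity at %s, row %d (value %s)",
                   cl, bad[1], as.character(x[bad[1]])), call. = FALSE)
    }
  }
  n_fallback <- 0L
  if (!"emotion_coded" %in% names(dat)) dat$emotion_coded <- NA_character_
  need_label <- which(is.na(dat$emotion_coded) | !nzchar(dat$emotion_coded))
  if (length(need_label)) {
    M <- as.matrix(dat[need_label, au_cols, drop = FALSE])
    colnames(M) <- as.character(human_au_ids())
    dat$emotion_coded[need_label] <-
      as.character(classify_expression_matrix(M, prototypes))
    n_fallback <- length(need_label)
    message(n_fallback,
            " row(s) lacked a coded emotion label; prototype classifier fallback used")
  }
  attr(dat, "n_label_fallback") <- n_fallback
  dat
}

#' Read an automated-coder CSV in the OpenFace column dialect
#'
#' Intensity columns `AU.._r` are parsed as reals; negative values are
#' clamped to 0 and values above 5 to 5, each with a warning. Rows with
#' `success == 0` are excluded and counted in the `"n_excluded_success"`
#' attribute; a missing `success` column keeps all rows with a warning.
#' Rows map to participant x emotion either through explicit
#' `participant_id` / `emotion` columns or through a `file` column following
#' the `<participant>_<emotion>` naming convention.
#'
#' @param path File path.
#' @return Tibble with `participant_id`, `emotion`, and `AU.._r` columns.
#' @export
read_openface_csv <- function(path) {
  dat <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  check_read_problems(dat, path)
  names(dat) <- trimws(names(dat))
  au_cols <- grep("^AU[0-9]{2}_r$", names(dat), value = TRUE)
  if (!length(au_cols)) {
    stop("no AU.._r intensity columns found in ", path, call. = FALSE)
  }
  if (!all(c("participant_id", "emotion") %in% names(dat))) {
    if ("file" %in% names(dat)) {
      base <- sub("\\.[^.]*$", "", basename(dat$file))
      parts <- strsplit(base, "_", fixed = TRUE)
      dat$participant_id <- vapply(parts, function(p)
        paste(p[-length(p)], collapse = "_"), character(1))
      dat$emotion <- vapply(parts, function(p) p[length(p)], character(1))
    } else {
      stop("cannot map rows to participant x emotion: need participant_id/emotion",
           " columns or a file column", call. = FALSE)
    }
  }
  for (cl in au_cols) {
    x <- dat[[cl]]
    if (anyNA(x)) {
      stop(sprintf("unparseable value in %s, row %d", cl, which(is.na(x))[1]),
           call. = FALSE)
    }
    if (any(x < 0)) {
      warning(sum(x < 0), " negative intensity value(s) in ", cl,
              " clamped to 0", call. = FALSE)
      x <- pmax(x, 0)
    }
    if (any(x > 5)) {
      warning(sum(x > 5), " intensity value(s) above 5 in ", cl,
              " clamped to 5", call. = FALSE)
      x <- pmin(x, 5)
    }
    dat[[cl]] <- x
  }
  n_excluded <- 0L
  if (!"success" %in% names(dat)) {
    warning("no `success` column; keeping all rows", call. = FALSE)
  } else {
    n_excluded <- sum(dat$success == 0)
    dat <- dat[dat$success != 0, , drop = FALSE]
  }
  attr(dat, "n_excluded_success") <- n_excluded
  dat
}

check_read_problems <- function(dat, path) {
  probs <- readr::problems(dat)
  if (nrow(probs)) {
    stop(sprintf("parse problem in %s at row %d: %s", path,
                 probs$row[1], probs$expected[1]), call. = FALSE)
  }
  invisible(TRUE)
}
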