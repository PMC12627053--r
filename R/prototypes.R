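EMOTIONS <- c("happiness", "sadness", "fear", "anger", "surprise", "disgust", "neutral")
BASIC_EMOTIONS <- EMOTIONS[1:6]

#' Prototype table for emotion classification
#'
#' A prototype table maps each basic emotion to its prototypical AU
#' combination, together with the scoring parameters used by
#' [score_match()] and [classify_expression()]. The default entries follow
#' the EMFACS-style prototypes (e.g. happiness = AU6+AU12+AU25); neutral is
#' the empty set by definition.
#'
#' @param prototypes Named list mapping each of the six basic emotions to an
#'   integer vector of AU ids. A `neutral` entry, if given, must be empty.
#' @param tau_active Activation threshold (intensity units): an AU counts as
#'   present when its intensity is at least this value. Default 1 (FACS
#'   "trace" level).
#' @param beta Off-template penalty weight (dimensionless) in the match
#'   score. Default 0.5.
#' @param s_min Minimum match score below which an expression is labelled
#'   neutral. Default 0.5.
#' @return An object of class `facedamp_prototypes`.
#' @export
#' @examples
#' tab <- default_prototypes()
#' tab$prototypes$happiness
prototype_table <- function(prototypes, tau_active = 1, beta = 0.5, s_min = 0.5) {
  if (is.null(prototypes$neutral)) prototypes$neutral <- integer()
  missing <- setdiff(BASIC_EMOTIONS, names(prototypes))
  if (length(missing)) {
    stop("prototype table lacks entries for: ", toString(missing), call. = FALSE)
  }
  if (length(prototypes$neutral)) {
    stop("the neutral prototype must be the empty AU set", call. = FALSE)
  }
  if (!all(c(6, 12, 25) %in% prototypes$happiness)) {
    stop("the happiness prototype must contain AU6, AU12 and AU25", call. = FALSE)
  }
  prototypes <- lapply(prototypes[EMOTIONS], function(p) sort(as.integer(p)))
  structure(
    list(prototypes = prototypes, tau_active = tau_active,
         beta = beta, s_min = s_min),
    class = "facedamp_prototypes"
  )
}

#' @rdname prototype_table
#' @export
default_prototypes <- function(tau_active = 1, beta = 0.5, s_min = 0.5) {
  prototype_table(
    list(
      happiness = c(6, 12, 25),
      sadness   = c(1, 4, 15),
      fear      = c(1, 2, 4, 5, 20, 26),
      anger     = c(4, 5, 7, 23),
      surprise  = c(1, 2, 5, 26),
      disgust   = c(9, 15, 16),
      neutral   = integer()
    ),
    tau_active = tau_active, beta = beta, s_min = s_min
  )
}

#' Read a prototype table from a plain-text file
#'
#' One entry per line, `emotion: au, au, au` (neutral may be given with an
#' empty list or omitted). Lines starting with `#` are ignored. Scoring
#' parameters are passed through to [prototype_table()].
#'
#' @param path File path.
#' @inheritParams prototype_table
#' @return A `facedamp_prototypes` object.
#' @export
read_prototype_table <- function(path, tau_active = 1, beta = 0.5, s_min = 0.5) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  entries <- list()
  for (ln in lines) {
    parts <- strsplit(ln, ":", fixed = TRUE)[[1]]
    if (length(parts) < 1 || !nzchar(trimws(parts[1]))) {
      stop("malformed prototype line: ", ln, call. = FALSE)
    }
    emo <- trimws(tolower(parts[1]))
    if (!emo %in% EMOTIONS) stop("unknown emotion in prototype file: ", emo, call. = FALSE)
    rhs <- if (length(parts) > 1) trimws(parts[2]) else ""
    aus <- if (nzchar(rhs)) as.integer(strsplit(rhs, "[,[:space:]]+")[[1]]) else integer()
    if (anyNA(aus)) stop("non-numeric AU id in prototype line: ", ln, call. = FALSE)
    entries[[emo]] <- aus
  }
  prototype_table(entries, tau_active = tau_active, beta = beta, s_min = s_min)
}

#' @export
print.facedamp_prototypes <- function(x, ...) {
  cat("<facedamp prototype table>\n")
  for (e in EMOTIONS) {
    aus <- x$prototypes[[e]]
    cat(sprintf("  %-9s %s\n", e,
                if (length(aus)) paste0("AU", aus, collapse = "+") else "(none)"))
  }
  cat(sprintf("  tau_active = %g, beta = %g, s_min = %g\n",
              x$tau_active, x$beta, x$s_min))
  invisible(x)
}
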