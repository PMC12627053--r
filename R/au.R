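#' Action Unit id sets
#'
#' `human_au_ids()` returns the 45 Action Unit ids a certified FACS coder
#' scores from still photographs. `openface_au_ids()` returns the 17 AUs for
#' which the OpenFace automated coder emits continuous intensity estimates
#' (the `AU.._r` columns of its output files); this is the default
#' comparison set for human-machine agreement.
#'
#' @return Integer vector of AU ids.
#' @export
#' @examples
#' openface_au_ids()
human_au_ids <- function() 1:45

#' @rdname human_au_ids
#' @export
openface_au_ids <- function() {
  c(1L, 2L, 4L, 5L, 6L, 7L, 9L, 10L, 12L, 14L, 15L, 17L, 20L, 23L, 25L, 26L, 45L)
}

#' Construct a validated AU intensity vector
#'
#' An AU vector records one rater's intensity coding of one face image: a
#' named numeric vector over a fixed AU id set, with 0 meaning the AU is
#' absent and 1-5 the FACS intensity levels (A-E). AUs not supplied are
#' treated as absent (0). Human codings must be whole numbers; machine
#' codings may be any real value in [0, 5].
#'
#' @param values Named numeric vector; names are AU ids (e.g. `c("6" = 4)`).
#' @param rater `"human"` or `"machine"`.
#' @param au_ids The supported AU id set.
#' @return Named numeric vector of length `length(au_ids)`.
#' @export
#' @examples
#' au_vector(c("6" = 4, "12" = 3, "25" = 2))
au_vector <- function(values = numeric(), rater = c("human", "machine"),
                      au_ids = human_au_ids()) {
  rater <- match.arg(rater)
  out <- setNames(numeric(length(au_ids)), as.character(au_ids))
  if (length(values)) {
    ids <- names(values)
    if (is.null(ids)) stop("`values` must be named by AU id", call. = FALSE)
    unknown <- setdiff(ids, names(out))
    if (length(unknown)) {
      stop("AU id(s) not in the supported set: ", toString(unknown), call. = FALSE)
    }
    if (any(values < 0 | values > 5)) {
      stop("AU intensities must lie in [0, 5]", call. = FALSE)
    }
    if (rater == "human" && any(values != round(values))) {
      stop("human AU intensities must be integers 0-5", call. = FALSE)
    }
    out[ids] <- as.numeric(values)
  }
  attr(out, "rater") <- rater
  out
}

#' Bin a continuous machine intensity onto the 0-5 ordinal scale
#'
#' Rounds half away from zero to the nearest integer and clamps to
#' \[0, 5\], so that the machine coding can enter categorical agreement
#' statistics alongside the human ordinal coding.
#'
#' @param x Numeric vector of non-negative machine intensities.
#' @return Integer vector in 0..5.
#' @export
#' @examples
#' bin_machine_intensity(c(1.5, 5.7, 0.49))
bin_machine_intensity <- function(x) {
  if (any(x < 0, na.rm = TRUE)) {
    stop("machine intensities must be non-negative", call. = FALSE)
  }
  as.integer(pmin(5, floor(x + 0.5)))
}
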