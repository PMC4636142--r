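#' Per-minute locomotor activity for one fly
#'
#' Wraps a uniformly sampled vector of 1-minute beam-break counts together
#' with the light schedule needed to attribute minutes to day or night.
#' Recording is assumed to start at \code{start} o'clock; under constant
#' darkness (\code{dd = TRUE}) the carried clock times define subjective
#' day and night.
#'
#' @param counts non-negative integer counts, one per minute, no gaps
#'   (missing values are rejected as non-uniform sampling).
#' @param fly_id,genotype,sex identifiers carried through to reports.
#' @param lights_on,lights_off clock times "HH:MM" of the light schedule.
#' @param dd TRUE for constant darkness.
#' @param start clock time "HH:MM" of the first sample.
#' @return object of class \code{activity_series}.
#' @export
activity_series <- function(counts, fly_id = "fly1", genotype = NA_character_,
                            sex = NA_character_, lights_on = "09:00",
                            lights_off = "21:00", dd = FALSE,
                            start = lights_on) {
  if (any(is.na(counts))) stop("non-uniform sampling: missing minutes")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  if (length(counts) < 1L) stop("empty series")
  structure(list(counts = as.integer(counts), fly_id = fly_id,
                 genotype = genotype, sex = sex,
                 lights_on = parse_clock(lights_on),
                 lights_off = parse_clock(lights_off),
                 dd = isTRUE(dd), start = parse_clock(start)),
            class = "activity_series")
}

#' @export
print.activity_series <- function(x, ...) {
  cat("activity_series:", x$fly_id,
      sprintf("(%s, %s)", x$genotype, x$sex), "\n")
  cat(" ", length(x$counts), "minutes (", length(x$counts) / 1440,
      "days),", if (x$dd) "DD" else "LD", "\n")
  invisible(x)
}

# "HH:MM" -> minutes after midnight
parse_clock <- function(x) {
  if (is.numeric(x)) return(as.integer(x))
  p <- as.integer(strsplit(x, ":", fixed = TRUE)[[1]])
  p[1] * 60L + p[2]
}

# logical vector: is each minute of the series in the light (day) phase
is_day_minute <- function(a) {
  mod <- (a$start + seq_along(a$counts) - 1L) %% 1440L
  if (a$lights_on <= a$lights_off)
    mod >= a$lights_on & mod < a$lights_off
  else
    mod >= a$lights_on | mod < a$lights_off
}
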