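#' Detect sleep bouts
#'
#' Sleep is behavioral quiescence longer than five minutes: a maximal run
#' of consecutive zero-count minutes of duration >= \code{min_bout} (the
#' field-standard reading for 1-min binned data; set \code{strict = TRUE}
#' to require strictly more than \code{min_bout} minutes). Bouts spanning
#' the light transition keep their identity; phase is attributed per
#' minute by \code{\link{sleep_metrics}}.
#'
#' @param a an \code{\link{activity_series}}.
#' @param min_bout minimum bout length in minutes.
#' @param strict if TRUE, require duration > \code{min_bout}.
#' @return data.frame with one row per bout: \code{start} (1-based minute
#'   index), \code{duration} (minutes), \code{phase} (day/night at onset).
#' @export
detect_sleep <- function(a, min_bout = 5, strict = FALSE) {
  stopifnot(inherits(a, "activity_series"))
  r <- rle(a$counts == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values &
    (if (strict) r$lengths > min_bout else r$lengths >= min_bout)
  day <- is_day_minute(a)
  data.frame(start = starts[keep], duration = r$lengths[keep],
             phase = ifelse(day[starts[keep]], "day", "night"),
             stringsAsFactors = FALSE)
}

#' Daily sleep metrics
#'
#' Totals are minutes of sleep per 24 h, averaged over the recorded full
#' days; minutes of a bout spanning the light transition are attributed
#' phase-wise, so day + night sleep equals total sleep exactly. Bout
#' counts and mean durations are per 24 h by onset phase.
#'
#' @param bouts \code{\link{detect_sleep}} result.
#' @param a the \code{\link{activity_series}} the bouts came from.
#' @return list with \code{total,day,night} (sleep min / 24 h),
#'   \code{n_bouts_day,n_bouts_night} (per 24 h),
#'   \code{bout_len_day,bout_len_night} (mean minutes), \code{n_days}.
#' @export
sleep_metrics <- function(bouts, a) {
  stopifnot(inherits(a, "activity_series"))
  n_days <- floor(length(a$counts) / 1440)
  if (n_days < 1) stop("need at least one full recorded day")
  used <- n_days * 1440L
  asleep <- rep(FALSE, used)
  for (i in seq_len(nrow(bouts))) {
    idx <- bouts$start[i]:(bouts$start[i] + bouts$duration[i] - 1L)
    asleep[idx[idx <= used]] <- TRUE
  }
  day <- is_day_minute(a)[seq_len(used)]
  in_window <- bouts$start <= used
  by_phase <- function(ph) {
    sel <- in_window & bouts$phase == ph
    list(n = sum(sel) / n_days,
         len = if (any(sel)) mean(bouts$duration[sel]) else 0)
  }
  d <- by_phase("day"); n <- by_phase("night")
  list(total = sum(asleep) / n_days,
       day = sum(asleep & day) / n_days,
       night = sum(asleep & !day) / n_days,
       n_bouts_day = d$n, n_bouts_night = n$n,
       bout_len_day = d$len, bout_len_night = n$len,
       n_days = n_days)
}

#' Waking activity index
#'
#' Beam-break counts per waking minute: total counts divided by recorded
#' minutes not spent asleep. Distinguishes true hypo/hyperactivity from
#' changes in sleep amount.
#'
#' @param a an \code{\link{activity_series}}.
#' @param bouts \code{\link{detect_sleep}} result for the same series.
#' @return counts per waking minute; 0 with a warning if the fly never
#'   wakes.
#' @export
activity_index <- function(a, bouts) {
  stopifnot(inherits(a, "activity_series"))
  wake_min <- length(a$counts) - sum(bouts$duration)
  if (wake_min <= 0) {
    warning("no waking minutes: activity index undefined, reported as 0")
    return(0)
  }
  sum(a$counts) / wake_min
}
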