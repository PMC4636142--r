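#' Configuration for the locomotor-activity simulator
#'
#' Defaults emulate a standard DAMS experiment: 16 flies per group, 1-min
#' bins, a free-running period near the wild-type 23.5 h, high-amplitude
#' rest/activity dichotomy for rhythmic flies, and sleep bouts embedded as
#' explicit zero runs so the 5-minute sleep rule has exact truth. Sleep
#' assays use 6 LD days; circadian assays use 14+ DD days.
#'
#' @param n_flies flies per group.
#' @param days recording length in days.
#' @param period_h free-running period (hours) of rhythmic flies; must lie
#'   in (14, 34).
#' @param amplitude rhythm strength in [0, 1]: 0 makes every fly
#'   arrhythmic (no phase modulation of activity or sleep), 1 fully
#'   phase-locks both.
#' @param rhythmic_fraction fraction of flies simulated as rhythmic.
#' @param mean_activity mean beam-break counts per waking minute.
#' @param sleep_mean_night,sleep_mean_day mean sleep-bout length (min).
#' @param wake_mean_night,wake_mean_day mean waking-bout length (min).
#' @param dd TRUE for constant darkness (circadian assay), FALSE for
#'   LD 12:12 (sleep assay).
#' @param lights_on clock time of lights-on.
#' @param seed integer RNG seed; fixed seed gives bit-identical output.
#' @return list of class \code{activity_sim_config}.
#' @export
activity_sim_config <- function(n_flies = 16, days = 14, period_h = 23.5,
                                amplitude = 0.9, rhythmic_fraction = 1,
                                mean_activity = 2,
                                sleep_mean_night = 40, sleep_mean_day = 15,
                                wake_mean_night = 12, wake_mean_day = 60,
                                dd = TRUE, lights_on = "09:00", seed = 1) {
  stopifnot(n_flies >= 1, days >= 1,
            amplitude >= 0, amplitude <= 1,
            rhythmic_fraction >= 0, rhythmic_fraction <= 1,
            mean_activity > 0, sleep_mean_night > 1, sleep_mean_day > 1,
            wake_mean_night > 1, wake_mean_day > 1)
  if (rhythmic_fraction > 0 && amplitude > 0 &&
      (period_h <= 14 || period_h >= 34))
    stop("period_h must lie in (14, 34) for rhythmic flies")
  structure(as.list(environment()), class = "activity_sim_config")
}

#' Simulate per-minute locomotor activity with known truth
#'
#' Rhythmic flies alternate between waking bouts (Poisson counts whose rate
#' is a thresholded sinusoid at the configured period) and sleep bouts
#' (explicit zero runs); bout lengths are geometric with phase-dependent
#' means, interpolated by \code{amplitude} between the phase-free average
#' and the full day/night split. Arrhythmic flies use the phase-free
#' averages throughout. With \code{amplitude = 0} every fly is arrhythmic
#' in truth regardless of \code{rhythmic_fraction}.
#'
#' @param cfg an \code{\link{activity_sim_config}}.
#' @return list of class \code{activity_sim}: \code{flies} (list of
#'   \code{\link{activity_series}}), \code{truth} (fly_id, rhythmic,
#'   period_h, bout-parameter columns), \code{config}.
#' @export
gen_activity <- function(cfg) {
  stopifnot(inherits(cfg, "activity_sim_config"))
  set.seed(cfg$seed)
  n_min <- as.integer(round(cfg$days * 1440))
  rhythmic <- stats::runif(cfg$n_flies) < cfg$rhythmic_fraction
  if (cfg$amplitude == 0) rhythmic[] <- FALSE
  flies <- vector("list", cfg$n_flies)
  for (i in seq_len(cfg$n_flies)) {
    counts <- simulate_fly_counts(n_min, rhythmic[i], cfg)
    flies[[i]] <- activity_series(
      counts, fly_id = sprintf("fly%02d", i),
      lights_on = cfg$lights_on,
      lights_off = (parse_clock(cfg$lights_on) + 720L) %% 1440L,
      dd = cfg$dd, start = cfg$lights_on)
  }
  truth <- data.frame(
    fly_id = vapply(flies, `[[`, "", "fly_id"),
    rhythmic = rhythmic,
    period_h = ifelse(rhythmic, cfg$period_h, NA_real_),
    sleep_mean_night = cfg$sleep_mean_night,
    sleep_mean_day = cfg$sleep_mean_day,
    wake_mean_night = cfg$wake_mean_night,
    wake_mean_day = cfg$wake_mean_day,
    stringsAsFactors = FALSE)
  structure(list(flies = flies, truth = truth, config = cfg),
            class = "activity_sim")
}

# two-state (wake/sleep) Markov simulation at 1-min resolution
simulate_fly_counts <- function(n_min, rhythmic, cfg) {
  t <- seq_len(n_min) - 1L
  A <- if (rhythmic) cfg$amplitude else 0
  # subjective phase: sin > 0 is subjective day, starting at "dawn"
  s <- if (rhythmic) sin(2 * pi * t / (cfg$period_h * 60)) else rep(0, n_min)
  night <- s < 0
  mean_sleep_avg <- (cfg$sleep_mean_night + cfg$sleep_mean_day) / 2
  mean_wake_avg <- (cfg$wake_mean_night + cfg$wake_mean_day) / 2
  mean_sleep <- (1 - A) * mean_sleep_avg +
    A * ifelse(night, cfg$sleep_mean_night, cfg$sleep_mean_day)
  mean_wake <- (1 - A) * mean_wake_avg +
    A * ifelse(night, cfg$wake_mean_night, cfg$wake_mean_day)
  p_fall_asleep <- 1 / mean_wake
  p_wake_up <- 1 / mean_sleep
  asleep <- logical(n_min)
  state <- FALSE
  u <- stats::runif(n_min)
  for (i in seq_len(n_min)) {
    state <- if (state) u[i] >= p_wake_up[i] else u[i] < p_fall_asleep[i]
    asleep[i] <- state
  }
  # waking counts: Poisson with thresholded-sinusoid rate
  rate <- cfg$mean_activity * pmax(0, 1 + A * s)
  counts <- stats::rpois(n_min, rate)
  counts[asleep] <- 0L
  counts
}

#' Write activity series as a Trikinetics-dialect monitor file
#'
#' One row per minute, tab-delimited: record index, date (dd mon yy), time
#' (HH:MM:SS), nine status fields, then one count column per fly/channel.
#'
#' @param flies list of \code{\link{activity_series}} of equal length.
#' @param path output file.
#' @param start_date Date of the first record.
#' @return invisibly, \code{path}.
#' @export
write_monitor_file <- function(flies, path, start_date = as.Date("2015-01-05")) {
  stopifnot(length(flies) >= 1L)
  n <- length(flies[[1]]$counts)
  if (!all(vapply(flies, function(f) length(f$counts), 0L) == n))
    stop("all flies must have equal recording length")
  counts <- vapply(flies, `[[`, integer(n), "counts")
  start_min <- flies[[1]]$start
  minute <- (start_min + seq_len(n) - 1L)
  day_off <- minute %/% 1440L
  mod <- minute %% 1440L
  dates <- format(start_date + day_off, "%d %b %y")
  times <- sprintf("%02d:%02d:00", mod %/% 60L, mod %% 60L)
  status <- paste(c(1L, rep(0L, 8L)), collapse = "\t")
  lines <- paste(seq_len(n), dates, times, status,
                 apply(counts, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read a Trikinetics-dialect monitor file
#'
#' Verifies that rows are consecutive minutes (a gap raises a non-uniform
#' sampling error) and returns one \code{\link{activity_series}} per count
#' channel.
#'
#' @param path monitor file written in the dialect of
#'   \code{\link{write_monitor_file}}.
#' @param lights_on,lights_off,dd light schedule to attach (the monitor
#'   file itself carries no schedule).
#' @return list of \code{\link{activity_series}}.
#' @export
read_monitor_file <- function(path, lights_on = "09:00",
                              lights_off = "21:00", dd = FALSE) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 13L) stop("not a monitor file: expected >= 13 columns")
  tm <- strptime(paste(df[[2]], df[[3]]), format = "%d %b %y %H:%M:%S",
                 tz = "UTC")
  if (any(is.na(tm))) stop("unparseable timestamps in ", path)
  dmin <- diff(as.numeric(tm)) / 60
  if (any(dmin != 1)) stop("non-uniform sampling: gaps in monitor file")
  start <- tm[1]$hour * 60L + tm[1]$min
  counts <- df[, 13:ncol(df), drop = FALSE]
  lapply(seq_len(ncol(counts)), function(i)
    activity_series(counts[[i]], fly_id = sprintf("ch%02d", i),
                    lights_on = lights_on, lights_off = lights_off,
                    dd = dd, start = start))
}
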